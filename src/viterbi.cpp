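#include <Rcpp.h>
using namespace Rcpp;

// Local Viterbi scan of one protein against a profile HMM, in log2-odds.
//
// prot: residue indices 1..20, or NA/-1 for masked positions (already claimed
//       by a previous hit; no state may emit them).
// lodM: L x 20 match emission log2-odds against the background.
// ltr:  (L-1) x 7 log2 transition probabilities, columns
//       MM, MI, MD, IM, II, DM, DD for transitions out of node k (k = 1..L-1).
//       Insert emissions equal the background (log-odds 0).
// entry: log2 entry probability into any match state (uniform local entry);
//        exit from any match state is free.
//
// Returns best score, the envelope (1-based, inclusive residue positions),
// and for each match state the residue position it emits (0 = delete,
// NA = outside the aligned core).
// [[Rcpp::export]]
List viterbi_local(IntegerVector prot, NumericMatrix lodM, NumericMatrix ltr,
                   double entry) {
  const int n = prot.size(), L = lodM.nrow();
  const double NEG = -1e30;
  // DP over i = 0..n (residues consumed), k = 1..L
  // VM[i][k]: best path ending in M_k emitting residue i
  std::vector<std::vector<double>> VM(n + 1, std::vector<double>(L + 1, NEG)),
      VI(n + 1, std::vector<double>(L + 1, NEG)),
      VD(n + 1, std::vector<double>(L + 1, NEG));
  // back-pointers: 0 = entry, 1 = from M, 2 = from I, 3 = from D
  std::vector<std::vector<signed char>> BM(n + 1, std::vector<signed char>(L + 1, -1)),
      BI(n + 1, std::vector<signed char>(L + 1, -1)),
      BD(n + 1, std::vector<signed char>(L + 1, -1));
  const int MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6;
  for (int i = 1; i <= n; ++i) {
    const bool masked = (prot[i - 1] == NA_INTEGER || prot[i - 1] < 1);
    const int xi = masked ? 0 : prot[i - 1] - 1;
    for (int k = 1; k <= L; ++k) {
      // M_k emits residue i
      if (!masked) {
        double best = entry;  // local begin -> M_k
        signed char who = 0;
        if (k > 1) {
          const double fm = VM[i - 1][k - 1] + ltr(k - 2, MM);
          if (fm > best) { best = fm; who = 1; }
          const double fi = VI[i - 1][k - 1] + ltr(k - 2, IM);
          if (fi > best) { best = fi; who = 2; }
          const double fd = VD[i - 1][k - 1] + ltr(k - 2, DM);
          if (fd > best) { best = fd; who = 3; }
        }
        VM[i][k] = best + lodM(k - 1, xi);
        BM[i][k] = who;
        // I_k emits residue i (insert after node k, k < L)
        if (k < L) {
          double bi = VM[i - 1][k] + ltr(k - 1, MI);
          signed char wi = 1;
          if (VI[i - 1][k] + ltr(k - 1, II) > bi) {
            bi = VI[i - 1][k] + ltr(k - 1, II);
            wi = 2;
          }
          VI[i][k] = bi;  // insert emission log-odds = 0
          BI[i][k] = wi;
        }
      }
      // D_k consumes no residue
      if (k > 1) {
        double bd = VM[i][k - 1] + ltr(k - 2, MD);
        signed char wd = 1;
        if (VD[i][k - 1] + ltr(k - 2, DD) > bd) {
          bd = VD[i][k - 1] + ltr(k - 2, DD);
          wd = 3;
        }
        VD[i][k] = bd;
        BD[i][k] = wd;
      }
    }
  }
  // best end: any M_k at any i (free exit)
  double best = NEG;
  int bi = -1, bk = -1;
  for (int i = 1; i <= n; ++i)
    for (int k = 1; k <= L; ++k)
      if (VM[i][k] > best) { best = VM[i][k]; bi = i; bk = k; }
  if (bi < 0 || best <= NEG / 2)
    return List::create(_["score"] = R_NegInf);
  // traceback
  IntegerVector matchPos(L, NA_INTEGER);
  int i = bi, k = bk, state = 0;  // 0 = M, 1 = I, 2 = D
  int envStart = bi, envEnd = bi;
  bool done = false;
  while (!done) {
    if (state == 0) {
      matchPos[k - 1] = i;
      envStart = i;
      signed char w = BM[i][k];
      if (w == 0) { done = true; break; }
      // predecessor of M_k emitting residue i sits at (i-1, k-1)
      state = (w == 1) ? 0 : (w == 2) ? 1 : 2;
      --i; --k;
    } else if (state == 1) {
      signed char w = BI[i][k];
      --i;
      state = (w == 1) ? 0 : 1;
    } else {
      matchPos[k - 1] = 0;  // delete
      signed char w = BD[i][k];
      --k;
      state = (w == 1) ? 0 : 2;
    }
  }
  return List::create(_["score"] = best, _["env_start"] = envStart,
                      _["env_end"] = envEnd, _["match_pos"] = matchPos);
}
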