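# STOCKHOLM 1.0

synthdom01  CVGIWMQNPFANLQNKGRNNIIAHIRFKRHSGNILAMTPQPLAEG
synthdom02  ----------ADLQNCGIENLIAPIRFTGEDGNILAMTTQPLAEY
synthdom03  ----------ADLMNCGIENLIAPRRFEGESGNILAMTTQSLAEE
synthdom04  ----------ADLQNCVIENLIQPIRFERESGYILAMTTQSLAEE
synthdom05  CVGIWPQGPFADMNNCGIKNLIAPIRFERESGNCLAITTQPLCEE
synthdom06  ----------ADLQNCGIMNLIAPIRFERESGNILTMTTQCLAEE
synthdom07  CVGIWMKGPWADHQNCGIENLIAPIRFERESGNIMAMSTQPLGEE
synthdom08  CVGIWMQAEFADLQNCGIENLIAPIRFERQSGNLLAHTTQPLAEE
synthdom09  CVAIWMQGPFADLQNCGIENLIAPIRFERESGNILAVTTQPLATE
synthdom10  CVGIWMQGPFADLQNCGIENLIAPIRDERELGNILAMTTQPLAES
synthdom11  ----------ADLQNCGIENIIAPIRFERESGNVLAMTTQPLAEE
synthdom12  CVGIWMQGPFADLQNCGIENLIAEIRFERESGNILQRTTQPLAEE
synthdom13  CVGIWMQGPFADLQNCGDQNVIAPIRFERESGNILAMTTQPIAEE
synthdom14  CVGMWMQGPFADLQNCGIENLIAPIRFERQSGDLFAMTTQPLAEE
synthdom15  ----------QDLQNCGIENLLAPIRFERESWNALAMTTQPLAEE
synthdom16  AVGIWMQGPFADLQNCGCDNLYAHIRFEREQCNTLAMTTQPLAEE
synthdom17  CVGIWMQGPFADLQNCGIENLIAPIRFHRESGNILAMTTQFLAEE
synthdom18  YVGIWMQGPFADIQNCGIENLIAPIRFDEESGNILAMTTQPFAEE
synthdom19  TVGIWENGPFADLQNCGIENLIEPIRYEIESGNNLAMYTQPLAEE
synthdom20  CVKIWMQGPFADLQNCWRENLIAPIRFERESGHILPMTTQPLAEE
synthdom21  CVGIWMQGPFLDLQCCGIENLIAPIRFERESGNILAMTTQPLAEE
synthdom22  CVGIWMQGHFADLQNCQIENLIAPIRFERESSNIVAWTTQPLAEE
synthdom23  CVGIWMQFPFADLQNCGIENLIKPIRYERESVNIAAMTTQPLAEE
synthdom24  RVGFWLQGPFAGLQNCNIENLINPIRFERESGDILAMTTQMLIEE
synthdom25  CVGIWMQGPFHHLQNCGIRNNIAPIRFERHSGNILAMRTQPLAEE
synthdom26  CVGHWMQGPFADLQTYGIDNLIAPIRFEREGGNILAMKTQPLWEE
synthdom27  CPGIWMQGPAADLDNCGIENLIAPIRSERESGNIMAMTTQPLAEE
synthdom28  GVGIWMQGPFSDLDNIGIENLIAPIRFERESGNILAMFTQPDAEE
synthdom29  CVGIWMQGPFAELQNCGIQNLIAPIRFERESGNILAMTCQPLVEE
synthdom30  CVGIWMQGPFADLQNYGIENLIAPIRFERESSNILAMMTQPLSEE
synthdom31  CVGIWMQGPFADLQNCGIENATAPIRFERETGNILAMTTQPLAEE
synthdom32  MVGIWMQGPFADLQNCSIENLVARLRFERQSGNILAMTTQPLAEE
synthdom33  CVGIWMQGPFADVQNCGCENLIAPIRFERVSGNILAMTSQPLATN
synthdom34  CVTIWMQGPFADLPYCGIENLIAPIRYERGSGNILAMTTQPLAEE
synthdom35  CVGIWMQGQFASLQNCGIENEIANIRFERESGNILAMTTQPLAEE
synthdom36  CVQIWMQGVFADLQNCTIENLIAQIRFERESGNILAMTTQQLEEE
synthdom37  CVGIWMQGPFADLQNCGIENLIAPIRFERESGNILAMTTQPLSEE
synthdom38  CVGRWMQGPMADMQNCPDENLIAPIRFERETGNILAMQTQPVAEE
synthdom39  ----------ADLQNCGIENLIMPIRFERETGNILMMTTQQLAEE
synthdom40  ----------ADLQNCGILNLIAPCRFERESGGVLAMSTQPLAEE
//
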