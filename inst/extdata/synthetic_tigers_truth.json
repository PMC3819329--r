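[{"id":"KTR_05","source":"NSTR","labelled":"KTR"},{"id":"KTR_10","source":"NSTR","labelled":"KTR"},{"id":"PTR_01","source":"KTR","labelled":"PTR"},{"id":"KTR_07","source":"MTR","labelled":"KTR"},{"id":"NSTR_03","source":"NGWLS","labelled":"NSTR"}]
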