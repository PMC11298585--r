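>SulTE_synthetic_reference
RHEVYTVEEYLEHVWEQPVDPGKQSSSSTSVTRLKIEARVAKVTLKRPTPNLKARADDAGDRYVYADAILKNRTLKGLII
LNEGAEEDLPKGRAQCNNVGPVRVADFWRQDQEAVNTTGSNRSPIARSPLNKIDKRVLLGDARIDFEAMVSFSVTASQLH
FQPMNAVKDKIHGMNVALLKEGQLVNQNFFVDIQSMSYAYGTDDTMSVEATSLAIDYLKSRWWQPAGATDLYLHDDQLLL
RPPNKSELVGQGPCIGLVQMLK
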