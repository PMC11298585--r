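>posII_1
RHFVYTVEEYLEHVWEQPMDPGKGSSSSTSVTRKAIEARVAKVTLKRATPNLKARADDAGDRYVYADAILKNRTLGGLII
LNEGAEEDLPKGRAQCNNVGPVRVADFWRQNQEAVNTTGSNRSPIARSPFNKIDKRVLLVDARIDEAMVSFSVTASQLHF
QPLNAPKDKIHGMNVMLLKEGQLVIQNFFVDIQSMSYAIGTDDSMSVEWTSLAIDYLKSRWWQPAGATDLYLHDDMLLLR
PPNKSELVGQGPRIGLVQMLK
>posII_2
RHEVKTVSEYLTHVWEKPVDPGKQSSSSTSVTRLKIEARVAKVTLKRPTPGYKARADDAGDRYVYAHAILKKRTLKGLII
LNEGAEEDLPKGRAQCNNVGFVRVKDAWRQDQEARNTTSSNKSPTARSPLNKIDKRVLLGDARIDFEAMVSFSVTAQQLH
FQPMTAVKDKIHGMNVALLKEGQLVNQNFFVDVQSMSYAYGTDDGRSVEATSLAIDYLKSRWWQHAGATDLYLHDDQLLL
RPPNKSELVGQGPCIGLVQMLK
>posII_3
RHEVYTVEEMLEHWEQPVDPGKQSHSSTSVTRLKIEANVAKVTLKRPTPNLKARADDAGDRYPYADAILKNRTLKGLIIL
NSGAEEDLPKGRAQCNNVGPVRVADEWRQDQEAVKTTGSNRSPIARSPLNKIDKRVLVGDARIDFEAMVSFSVTASQHHF
QCQNAVKDSIHGMNVALLLEGQLFNQNFEVDIMSMSYAYFTDDTMSVEATVLAIDYLKFRWWQPAGATVLNLHDDQLLLR
PPNLSELVGQGPCIGLQQMLK
>posII_4
RHEVYTVEEYLEHRWEQPVDPGKQDSSSTSVTRLKIEARVAKVTLNRPTPNLKARADDAGDRYVYADAILANRTLKGLII
LNEGAEEDLPKGRCQCNNVGPVRVADFWRQDMEAVNTTGSNRSPIARSPLNKIDKRVLLGDARIDFEAMVSFSVTASPLH
FQPANAVKDKKHGMNVALLKIGQLVNQNFFVDISMSHADPTDDTMSVEATSLAIDYPKSRWWQPAGATDLYLHDDPLRLR
PPNHSELVGQGICIGLVQMLK
>posI_1
RFTENYTGEEYLEHVWEHPVPPGQQSSSSTCVHRLKCTARVNWIDLKRGTPHSKERADDFGIRYVAALAAQPNRKLKPLP
DLWETMEERTMKGRAQCVNAGPVHYAADHWRHDQEYVNPTGSNRDPIARSKLNKIDWRVLLGAERIDQEAMVQANVTCSD
LFEQPMNYVPDKIHGMNRALLNEHQLRHPTFFVDIGSSRCDMGTDATMIRPATHLPIDYGKHSWSCPGGAQNLYRHDDQR
FLRPVNKSNLQRQGPCIGLVEALE
>posI_2
LHTEVYVGDEYLEHVLEHPVPAGQQSSSSTCVTRAKCTARVNFIDLKTGTPHSKERADDDGDRYVAALAAQPNRYLKPLP
DMVETMEEDTMKGRAQCVRNGPVHVAADHWRHDQEYVNPTGSNLDPIARSKRNCIDWRVLLGAYRITQEAMVQATVTASL
LFEQPMNCVPDKIHGMNRALLNEHGLRHPTYVVHIGSPEYDMGTDATMIRPATHLPIDYGKHSWSQPGGAQNLYRHDDQR
KLMAVNKSELQRQGPCIGLTEALE
>posI_3
RHTEVYTGEEYNEHVWEHPVPPGQQSSASTCVTRLKCTARVNFIDLKRGTPHSKERADDFGDRYVAALAAQPNRKLKPLP
DLWETMEEDTMKGRAQCVNAGPCHVANDHWRHDQEYVNATGSNRDPIARSKCNAIDWFVLLGAERITQEAMVQANVTASL
LLQEQPMNCVPDKIHGMNRALLNIHQWRHPTFFVDIGSSRYDSGTDAQMIRPATHLPIDYGKHSWSQMGGACNLYRHDDQ
RKLRPVNKVELQRQGPCIGLTEALE
>posI_4
RHTEVYNGEEYLEHVWEHPVPPCQQSSSSTCYTRLKCTARVNFIDLKRATPHVKERADHFGDRYVAALAAQPNRKLKPGP
DLWKTMEELTMKGRAQCVNAGPVHVAADHWWHDQEYVNPTGSNRDPIKRSILNGIDWRVLLGAERIEQEAMVQANVTASL
IFEQPMNCVDDKIHGMNRYLLNEHQLRHPTFFVDIGVSRYDRNTDATMIRPATHLPIDSGKHSWNSQPGGAQNLYRHDDQ
RKLRPVYKSELQRQGPPIGLVEALE
>outgroup
GPGMAHQDESFNADMLGMIGAAYMYAPTLTTESIRFEAHLEELAEDMKALTPGPRMANQKEQRAVPQQLKLVWELKSDSE
SVGKVFQMAHTPWLEGIQPFLDKIETIIFSAVISQKLTGARAVKRRDVQEDKSMPRFMMFRHELHYTLDPTLIKRIRGGG
KPMRKRQIIIANNFGDMYTSIHINLEPGATAEVKVACNNIAQSMSVVNSCQQIIVLGDSDIRTDNGDTNYVSWTLEDKVS
TCGVIVYRERLMDAKIESRD
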