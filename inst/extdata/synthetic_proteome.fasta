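>SIPHO_100001 Siphonaptera
SLTRNRPGTPCVRAHGYGYNVTHGGRYRTTCAYICELEEDVRPAQHTMNRKWGDKHCLEA
QWRFGVKGDDEAKVRIDASCEANWVCWMIPKEDNHTNMQDQKGHNMMYMRYHYIVFMQAL
ELPYDGNSMWYRVNHCHWAPRCMSWCSTYRWSMGIAGEPFGAIHWLRWGLPNHGCDWGSM
KTNM
>CERAT_100002 Ceratopogonidae
MKLILVVVLFVFLVAQAQVSAQYIYMYPICRYDMEHNAIYQTRRGDDSMCDFEKADHPRS
IKCRWILKWIEHGPGGNSQIFAVRFCSKDPRMIQNDVDSFRTSGGDEMRAARYIDSYVFQ
RWFMEMPWQFATGFANNRPRTFQLNLCL
>CERAT_100003 Ceratopogonidae
MKIFILIFILVVIAQAHEMELVDVQYGVWGTPLAPCPILGYYAKSLNVWSSVQLMSRKWM
WYPPLYTDHGIHWNNISRHKTLTIGNWQRFIIQPHNVNLGSAHAARPAMQGEDQMWRGGL
KPKHTRKN
>CIMIC_100004 Cimicomorpha
MKLVIIVVIFILLLAQAMPDWETACQGTGVPDRKTTNDIKKILWAKYQNRTSLKLSEKWK
FENKLWGPIMFFLRDEHVNIQPIHCWAGPWGDWAWVMSPGPIPCSAVRNYPAGLFCHKAV
IQSHCEANAFTGSNHMFDERWKSIWWLICDRYMRSVGQQEHMKDQFYRWVKKTTMGCHAY
DK
>TABAN_100005 Tabanidae
MKIILVVFFLFFAQANVDGGTYGYQEWCEFQNLQFFLVFMWGDVWHLMDRDDIKRLAEIC
IKKPLVAFDGEALGLIIKIAAAIQTNAFYDMMSYAGQHIKGHAWMYPMWSVFDADFAFPF
VRWYDGLMLLHWFGDEFEGSDQTPTTPFWYWGINRPGRVKMKQNKKVTPYVILEPPGGDI
YA
>SIMUL_100006 Simuliidae
MKIVIIFILILFAQAEDGEGKADHADRRTTDLVQCQLNKTTTILFKIIVDVWYMVYIWRA
EFLCFPWNMHGCFLFMFYETLDFYPQAEDPGNKCHVMMPGRHHPQMKPVWPPMYPLNTSP
FFHDGRLIHTQQMRWPYCKCVASMCKDGVMHQWKFGLNFYPNWTFGRSSFAGPQE
>PSYCH_100007 Psychodidae
MKIVIIFLVVAQARAHGDQKGPRPYHTKNVSSREDLHSTAKNIGMNFESPVYPWSIVEVI
HFVGNADNDWFPRYYMPQLNAGFDNVDGKFIWMFCPQVDGNSSGPGHSSAFHRTSVIQIP
STISLPNSLCWPYQIYYGRNYIPDMFRFFFRLRLGMQHIRPVWDVNYLKMQLAVLALKLR
IIRKHFAHYN
>HIRUD_100008 Hirudinea
TKSRSRWGWTYQEQSGSNQDARPGGMFNYQQHCFCNSHSDRPMVGDLAPTAWWTFEVKTG
SCGERHSPTNGTTMGNIKGGPPKQAYRYHGMPQGPWISH
>SIPHO_100009 Siphonaptera
RDALEIYGTHLNKPTGGQAHEHNGKESICNIYKMMKRDLWVKYIVEEEKWDGLVATYREL
LTMDCDGQYRKKRDQFIHCWLVYGNLDSFAQDQDYYCHNAYMQNTRVGDMAGVSMQIDAC
QDHRANPKMDVHSIQMSLFLVKVKTDIRSQCDTPMQFQRKGTQSYMWCWVFHLHNYQGGN
AMNKQVFRSMKVAPKPHMSPNQIGAQEHDRPSRGYHRTMLGAVAICMILRDQVEQIAFRG
IPHQLAVSIMWHPPQKTFTQ
>TABAN_100010 Tabanidae
NECCWKSGPWYVPRFGQPFSQDHGLHIYRSDTQRPYRKCRGFANVMEIYWEYDFNKYVEL
KLASSVCIEYVSSIELRTDVNAMEKAMLHGVVPWPYFALNHDKRQWAPFLRQWGLLMYSF
CMDIHFFQQKNIIFARVGDWYQGAMCFWWDFLCKLSHHVWIKQDEDFCMNTSSCRKMPVT
PARFYYRKFVPDISL
>IXODO_100011 Ixodoidea
MKLIFLFLIIFAQARMVKVTLWMFNDVMSVEKRVEFIGDAACYWGAPWPWGDQTLAKPTN
FSETFLMCYYFMEPHISDICSQEGHSDREDVDKMRGNSKCYKPSVHYSWKATAETGEVQY
>HIRUD_100012 Hirudinea
MKCKGDCVIVFILILAQAVVTDRMIQNWHMGKYMHRAWRTSIQAVMDPIDLKNIQVLRKT
PWIVTADQPGEQYYWHFPYSNPLIPPKGWENDETYNPGFPGNPYASACHRIYKIHEAALW
IYQPEGHQFRLHAETGNRMGEGDEIHRVSLMIPLTR
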