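>synthetic_repeat_01
CLFIKVYDWEEIVMDVYKYSIVEIQDCWYTKDLKIKKIGYSGGDADWDGMAA
>synthetic_repeat_02
CLFGKKYDWEEHVMAVYFYSIVHIQDCWTTKRLKDCYIGIRGCMADWHPMVT
>synthetic_repeat_03
CSFIKKYDWELDVMAVYKYCRVLPNDCWEHRDPKHKKIGISGGAAVWAGVVT
>synthetic_repeat_04
EMFIKKYHWEQIVMARYKYSIEEINDCWKTQDLKIKPIGKSGGALTWAGMVT
>synthetic_repeat_05
PMFIKKYDWEVIVMAVAKRSIEFINDDWVIKFLKIKFIPTTGGAADWAGMVT
>synthetic_repeat_06
QLNIHKYDWEEPVMRVYKYYCVEANDCWYTHDLNDKLIPYCAGAADWAGMVT
>synthetic_repeat_07
CPFIKYYDWEEIVHAVGKYSDHEINDCWYTKDLKIKAYTYSGGAAYWAGRVM
>synthetic_repeat_08
CNKIKKYHWEEIGCAVYSQSIDYMHACWYTKDLKIKFILYSGRCCSWAGGGT
>synthetic_repeat_09
CLPIKKYDWGEIVMAVFKYLSVEINDCWYTKDLKIKKIGRMGGADDWHGMST
>synthetic_repeat_10
HLFGQKYDWCGLVMAFYRYRIMMLNDPWHTCDLKYKKIGYSGGAYAWARMFT
>synthetic_repeat_11
CLRPKCYDWEEITIAQYKYSIVEICLCWYTKDLKPGKIGYYGLAAKWMGMPT
>synthetic_repeat_12
VLPTIKYRWEEIVMMVYKKSIVEIKDCWYTKDLKYKKIIYQGGAADWALMVT
>synthetic_repeat_13
QLFIKYYDWEEIDMAVYNYSIVEIHDCWYTKDLKVYKIGNHGGAADWDQMVT
>synthetic_repeat_14
CLFIKKAYWEPIVTAVYYYSIIRINDQWYTKNLCIKKIGYSTGAKDWAGMST
>synthetic_repeat_15
CLFIKKYHWEHIVMHLYKYNIVEINDCWYTKNLEIVKIGYSGGASDWAGMCT
>synthetic_repeat_16
CLYPKIIDWAEQAMKVYKYMIVSINMCWYTKDLKIHKIGLSGSFADWAFMYA
>synthetic_repeat_17
NLFIHKYDWEEIDMFNYMYDSVEVCQCWYCQVLKIKKIGYSYGAADWYGMVT
>synthetic_repeat_18
PEHINKYDWQEIVMGVYKYSTVECNACWYTEDHKIKFIGYHLGAIQWAGMVT
>synthetic_repeat_19
YLFIKKYCWEEIVRVVYKYNIYGINCLWYCKDNELKIIGYHGGPLVWAGMHT
>synthetic_repeat_20
CLVNKKYDWEMIVMMVYNYLIVEINDNWYTDDLKIKKIGISGGAADWHGMVT
>synthetic_repeat_21
CRFMKKKDWEEQNMAHYKYSIPEINDCWYMKDLYIKKIRYSGGEADWAGMQT
>synthetic_repeat_22
CLFIKKLDWEQIFMAVYKYMHVVINLCWTTKDLKIKDIGNSQGCAIWAGMNT
>synthetic_repeat_23
CLFDKKYDWDEIVMTVYKYSIVEDNDCWYTCDLNIAKIGVSGGAPLWRGMVM
>synthetic_repeat_24
CLFIKAYDWECIVMAHYKYSIVEINPCWYTKDNKIKKIHIDGGAAYWAGFVT
>synthetic_repeat_25
TLFIKEYDWEEEGMHVGKYSIVFRNQCWETKTLKIKVIGNNGGYAFWAGMVL
>synthetic_repeat_26
CLFIHKQQWMEIKTTVYKYRIVCIHDCWYTKDYKTNKIGYSGVAADWAGMVT
>synthetic_repeat_27
CLNKKKTDWMEIVMAVYKYSIVEINDCWAVEDLKISSFGYSEKAADWNGMVY
>synthetic_repeat_28
DLPNFKYTWEEDVMAYPKYSIFECNIIWYTKDLKIMKINYEGGPADWAGMVT
>synthetic_repeat_29
CLLEKKYVWNEIHMAIYKYSPVEINDMWCTKKSKIKKIGYSGGAAKWAGMET
>synthetic_repeat_30
CLYIKKYDWPHAVMAVYGYSIFERNDCWYTKDLKACGIPYSGGLADWAGMVT
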