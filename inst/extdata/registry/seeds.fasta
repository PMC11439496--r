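>METE_seed1
RGWTVWCHPKALKVVVAAPNFGSVHGMSRCSHHMPNTRQCRKLKQRVQSWACPLREKDDL
SCFCTVCFMKDYKHGAFTVAREPGCDMVYQMWYDDCIAKDGYIQIGYEKCDNRKASEEMN
YVICH
>METE_seed2
RGWTVWCHPKALKVVVAAPNFGSVHGMSRCSHHMPNTRQCRKLTQRVQSWACPLREKWDL
STFCTVCFMKQYKHGAFTVAREPGCDMVYQMWYDGCIAKDGYIQIGYESCDNRKASMEMN
YVIAH
>METH_seed1
HGGHFYCNVDRLHGQPSQKNCYHHMQVINSKSFELYLNWFKGICMIDPAHNKWLAGRDSD
MYNERAKTPQANHWGGRWSAWDTERAIHCMKVMSKIQARGFKTATLPCCYSNRTICVSFR
DYDERAIWEYNMLNVASFSDIMPNAQPMAAKIDCGIQGTATTEPHIRNTHFEYCPYDPHD
MNYQYLMWRIAWPHFYAMFTHEKGRHNLNWWGIYTPRKFNLYDHILDQDKCWQMWDNVGY
QNHMATLCPDFYRCQRGAGKCQMWPAPYHFRHTNPGFIVQWMTQHSGVSM
>METH_seed2
HGGHFYCNVDRLHGQPSWFNCYHHMQVINSKSFELYLNWFKGICMIDPAHNKWLAGRDSD
DSNYRAKTPQANHWGGRWSAWDTERAIHCMNVMSKIQARGFKTATLPCCYSNRTICDSPR
DYDERAIWEYNMLNVASFSLIMPNAQPMAAKIDCGIQGTAKTEPHIRNTHFEYKPCDPHT
MWYQYLMWRIAWPHFYAMFTHEKGRHNLNWWGIYVPRKFNLYDHILDQDKCWQMWDNVGY
QNHMATLCPDFYRCQRGAGKCQMWPAPYHFRHTNPGFIVQWMTQHSGVYP
>MTRR_seed1
IHPHCVHRWWHFHLWNMTIFGKFYDAMSHFIYGRPMWNNIGPFRQQIFCQNFVNWAPSYK
GLRDLGPMHEYRPEAACHPHPTAYMVHEFGNDAEPENFKVGYIQYYSAGDDKDYCRGGVW
TYPTMWTWQKHTQCQMCYMRTMIEKWCYKCLSEYKVPQCMLGTSSWCGCHKTPQEEHSGC
>MTRR_seed2
IHPHCVHRWWHFELWNMTIFGKDYDAMSHFIYGMPMWNNIGPFRTQIFCQNFVNWAPSYK
GLRDLGPMHELRPEAACHMHPTAYMVHEFGNDAEPTNFKVGYIQVYSAGDDKDYCRFGVW
TYPTMWTWQKHTQCQMCYMRTMIEKWCYKCLSEYKVPQCMLGTSSWCGCHKYPQEEHSGC
>MCM_seed1
PGHHKNIEWRPNNADKIKFQPSISFRGYAKPSFTEEWVQHVYNTEVMFPEFWENMSSWTE
KGIAWPHLWEMNYQYLMWRIAWPHFYAMFTHEKGRHNLNWWGIYTPRKFNAHARWHEIGS
SVILE
>MCM_seed2
PGHQLNIEWRPNNADKIKFQPSISFRGYAKPSFTEEWVQHVYNTEVMFPEFWENMSSQTP
KKIAWVHLMEMNYQYLMWRIAWAHFYAMFTHEKGRHNLNWWGIYTPRKFNAHARWHEIGS
SVILE
>RNR-II_seed1
QMNFKWPLDILSSRIKNVCFSMGASVKQRCIKCHQCMNEQNMYLSGTAHARDSMINSRQI
KQCTKYCPPF
>RNR-II_seed2
QMNFKEPLDIDLSRIKNVCFSMGASVKQRCIKCHQCMNEQNMYLSGTAHARDSMINSRQI
KQCAKYCPPF
>CblA_seed1
QHDAYMFFIYLANFPSEEHVPPIGSQNEEAEAQWSGQKMGVVDDHQTRIITTGWFLYEVK
TAEMPRWDML
>CblA_seed2
QHDAYMFFIYLANFPSEEHVPPIGSQNEEAEAQWSGQKMGVVDDHQTRIITTGWFLYEVK
TAEMPRWEML
>CblB_seed1
KPDSTSLMVGDHMRQGFLCAEDFQFNDTHAPFAAYSATEADHPLEFKWCDHGLWGKHDQT
GKQCGHFGFM
>CblB_seed2
KIDSTSKMVGDHMRQGFLCAEDFQFNDTHAPFAAYSATEADHPLEFKWYDHGLWGKHDQT
GKWCTHFGFM
>CblC_seed1
RKLGMFKTRSNIHLWDRLRGYCYCTMRKRIMLEYCGDRSRPIVPAVWMFSMFEYCRINEM
GKRPLMYSLV
>CblC_seed2
RKLGMFKTRSNIRLWDRLRGYCYCTMRKRIMLEYCGDRSRPIVPAVWHFSMFEYCRINEM
GKRTTMYSLV
>CblD_seed1
PGSSTASYVDVIDFSSETEQLWGHMMKDMHDNEYAECWEVLDQVVMIRTKSDGYYWPYTY
RCVLICMCIE
>CblD_seed2
PGRSCASYVDVIDFSSETEQLWGHMMKDMHDVEYAECMEVLDQVVMIRTKSDGYYWPYTY
RYVLICMCSE
>CblF_seed1
YCEAFKCLKIWIRCKLEWPNPPHQMGCQRFDLNGSTQARVFNPYMAIDYVPPEGCLVQNC
TCRFIECGTR
>CblF_seed2
YCEAFKCLKIWIQCKIEWPNPPHQMGCQRFDLNGSTQARVFNPYMAIDYVPPEGCLVQNC
TCRFIECGTR
>CblJ_seed1
YMVWCPLFPTICIWLKCFKRICPAGQCPMRQMGRLAQYVYFYCSCWQCFISCRLKFGCMA
NAPNEKRDNK
>CblJ_seed2
YMVFCPLFPTICIWVKCFKRICPAGQCPMRQMGRLAQYVYFHCSCWQCFISCRLKFGCMA
NAENEKRDNK
>CblX_seed1
TYAPDRWHSQCPDYQTIKFPMNADLVQMLEMRYRELWIRIPPDTPTRNFMFHSHVCIRKT
NNTYIHGDND
>CblX_seed2
TYAPDRWHHQCPDYQTIKFPMNADLVQMLEMRYRELWIRIPPDTPTRNFMFHSHVCIRMT
NNTYIHGDND
>epi-CblC_seed1
ANRGRWNCCRIYNIQDRLRGYCYCTMRKRIMLEYCGDRSRPIVPAVWMFSMFEYCHNFFQ
HMLFNKWFDS
>epi-CblC_seed2
PHRGRWNCCRIANIQDPLTGYCYCTMRKRIMLEYCGDRSRPIVPAVWMFSMFEYCHNFFQ
HMLFNKPFDS
>CBA1_seed1
RGKHILRVSVWIIYFDQVYWSGTNMLTLNLCNMGLQPQGSFTQQCVQTDDGCGNHYDCWN
QEHPMFYKHNVQYLETKGLYQVHRPPEKGPNYCGCHWAMHIRKHNKYLHVSGAEPRQPDT
GDHEEICEQIYPYNCKLWCCFDNSFYIKTGGMNSIAIIMVFTPAFFYHGQIYVRHKTRIL
WSDREHAHSANFHQCMICIDPGEQQKYNMFAWAMILRIRLDAGFFEPKFSCTFFSMEMCE
GPNIWVRFAE
>CBA1_seed2
RCFCKRPLRVQPIYFLRNLQSWWWMVWKCNCEHMMQMWISNQQLEIHQDGAGGGECPTEG
QERYSYYCNNVQHAWEKQMYTMHKQEEQTFSYDYCVMEMFHMMQGDPPMVGAADVRIWPP
SDIAVTEVQCYYMSYKIDYKTNFSWYIYTGNYNWIACVMYFKDVFFMHVQWVVRHKWDFQ
VGCREFIVAFHYTAFMVPDSPGEQQFYNMFSWFMHPDHPLDYGFCEEKVSMMTFNYEMCT
VKQGWFGWSE
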