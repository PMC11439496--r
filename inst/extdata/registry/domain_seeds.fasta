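>PF08267|1
VAAPNFGSVHGMSRCSHHMPNTRQCRKLKQRVQSWACPLR
>PF08267|2
VTAPNFGSNHGMSRCSHHMPNTRQCRKLKQRVQMWACPLH
>PF08267|3
VAAPNFGSVHGMSRCSHHMPNTRQCRKLMQRVQSWACPLR
>PF01717|1
DYKHGAFTVAREPGCDMVYQMWYDDCIAKDGYIQIGYEKC
>PF01717|2
DYKHGAFTVAFDPGCDWVYQAWYDDCIAKDGTIQIRYEKC
>PF01717|3
DYKHGAFTVAREPGCDMVMQMWYDDCIAKDGYIQIGYEKC
>PF02574|1
PSQKNCYHHMQVINSKSFELYLNWFKGICMIDPAHNKWLA
>PF02574|2
PSQKNCYHHMQVICMKSFELMLNWFKGICMIDPAFNKWLA
>PF02574|3
PSQKRCYHHMQVINSKSFELRLNWFKGICMIDPQHNKCLH
>PF00809|1
ANHWGGRWSAWDTERAIHCMKVMSKIQARGFKTATLPCCY
>PF00809|2
ANPWGGRWSAWDTERAIHCMIVMSKIQARGFKPALLPCCY
>PF00809|3
ANHWGGRWSAWDTELAIHCMVVMSKIQARGFKTATLPCCY
>PF02607|1
AIWEYNMLNVASFSDIMPNAQPMAAKIDCGIQGTATTEPH
>PF02607|2
AIWEYNMLNVASFSDIMPNAQPMAAKIDCSIQGTATTEPH
>PF02607|3
AIWEYNMLNVASFSDIMPNAQPMAAKIDCGIQGTATTEPH
>PF02310|1
MNYQYLMWRIAWPHFYAMFTHEKGRHNLNWWGIYTPRKFN
>PF02310|2
MNYQYLMCRVAWIHFYAMFTHEKIRANLNWQGIYTPRKFN
>PF02310|3
MNYTYLMWRIAWPHFYAMFTHEKGRHNLNWWGIGTPRKFN
>PF02965|1
DNVGYQNHMATLCPDFYRCQRGAGKCQMWPAPYHFRHTNP
>PF02965|2
DNVGYANHMATLYPDFYRCQRGAGKCQMCPAPYHFRHTNP
>PF02965|3
DNCGYQNHMATLCPDFYRCQRGAGKCQMWPAPTHFRHTNP
>PF00258|1
NMTIFGKFYDAMSHFIYGRPMWNNIGPFRQQIFCQNFVNW
>PF00258|2
NMTIFGKFYDAMSHFIYGRPMWNNIGPYRQQIFCQVFVNW
>PF00258|3
NMTIFGKFYDAMSHFIYGRPMWNNIGPFRQQIFCQNFVNW
>PF00667|1
YRPEAACHPHPTAYMVHEFGNDAEPENFKVGYIQYYSAGD
>PF00667|2
YRPEAACHPHPTAYMVHEFGNDAEPQNFKVGYIQYYSAGD
>PF00667|3
YRKEAACHPHPWAYMVIEFGPDAEPTNFKVGYIQYYSAGD
>PF00175|1
WTWQKHTQCQMCYMRTMIEKWCYKCLSEYKVPQCMLGTSS
>PF00175|2
WTWQKHTQCQMCYMRTMIEKWCYKCLSMYKVPQCMLGTSS
>PF00175|3
WPWQKHTQCQMCQMRTMIEKWCYKCLQQYKVPQCMLRNSS
>PF01642|1
KIKFQPSISFRGYAKPSFTEEWVQHVYNTEVMFPEFWENM
>PF01642|2
KIKFQPSISFRGYGKPSFTEEWVQHVYNTEVMFPEDWENM
>PF01642|3
KCKFQPSISFRGYAEPSFTEEWVQHVYITAFMFPEFWENM
>PF02867|1
KNVCFSMGASVKQRCIKCHQCMNEQNMYLSGTAHARDSMI
>PF02867|2
KNVCFFMGASVKYRCIKCHQCMNEQNMYLSGCAHARDSMI
>PF02867|3
KNSCFGMGASVKQRCIKCHQCMNEQNMYLSGTAHARDSMI
>PF03308|1
SEEHVPPIGSQNEEAEAQWSGQKMGVVDDHQTRIITTGWF
>PF03308|2
AEEHVPPIGSQNEEAEAQWSGQKMVVVDDHQTRLIYTGWF
>PF03308|3
DEEHVPPIGSQNEEAEAQWSGQKMGVVDDHQTRIITTGFP
>PF01923|1
GFLCAEDFQFNDTHAPFAAYSATEADHPLEFKWCDHGLWG
>PF01923|2
GFLCAEDFQFNDTHAPFAAYSATEADHPLEFKWCDHGRWG
>PF01923|3
GFLCAEDFQFNDTHFPFAAYSATEADVILEFKWCDHILWG
>PF16690|1
DRLRGYCYCTMRKRIMLEYCGDRSRPIVPAVWMFSMFEYC
>PF16690|2
DRLRGYYYCTSRKRIMLLYCGDRSRPIVPAVWMFEMFEYC
>PF16690|3
DGLRGYCWCTMRKRIMLEYCGDRSRPIVPAVNMASMIEYC
>PF10229|1
SETEQLWGHMMKDMHDNEYAECWEVLDQVVMIRTKSDGYY
>PF10229|2
SETEQLWGWMMKDMHDFEYAECWEVLDQFVMKRTKSDGYY
>PF10229|3
SETEQLWGHIMKDMHDNEYAECWEVLDQVVMIRTCSDGYY
>PF04791|1
LEWPNPPHQMGCQRFDLNGSTQARVFNPYMAIDYVPPEGC
>PF04791|2
LEWPNPPHQMGCQRFDLNGSTQARVFNPYHAIDYVPPEGC
>PF04791|3
LEWGNPPHQMGCQRFDLNGSTQARVFNPYMAIDYVPPEGC
>PF00005|1
KCFKRICPAGQCPMRQMGRLAQYVYFYCSCWQCFISCRLK
>PF00005|2
KCFKRICPAGQCPMRQMGRLADYVYFYCSCWQCFISCRLK
>PF00005|3
KCFKRICPAGQCPMIQMGRLMQYVYFYCSCWQCFISCRLK
>PF13415|1
TIKFPMNADLVQMLEMRYRELWIRIPPDTPTRNFMFHSHV
>PF13415|2
PIKFPMNACLVQMLEMRYRELWIRIPPDTPTRNFMFHSHV
>PF13415|3
TIKFCMNADLVQFLAMRYRELWICIPPDTPTRNFMFHSHV
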