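>SYN0001
FRILNQDAPMIMWFEYWMAELPQCGQNCYLWFFGGAFKFPYGTWPHDVQCTNPCSQYWFEGPKHSYLMFSPPGVGPHYPLRQDWEKDRMSMIMYSDWMHPGNNWYIYVEAPPYADNRQVLKRKHFWMVRVLVTVEWFMM
>SYN0002
WIPHDHDPAGITMFPPDLECWARETARVWCPYQVFNRCMMQKWVKSPCRYSLNEQLSTLFGIGIHFLFYLFEPKAWAGYRRRDIMEIFDARKGRQAGNNAGDVESDLSHDPHIHKKWVGINSALVKSAQLEGSKASRMPLRSNNF
>SYN0003
ERDLNSFSWATLWLGYHSGWDQRGNQCSRMRFDHDTCSSPPQQKFQGAVYFWNTQNSQCYPHYKTAAFCGALYQWRFRYYMAKWLKTYDFMWYMFEMKDGFLLNNYLFMQLPFHSANSGFFIHVFYNADFVNAMEDKQRWSW
>SYN0004
PGEDQMVETMSLRMFCIALCANWWFRHMAKVGNYTFQCWAYCDEAQTRHPNWKRWRMSGPFGLIIGSKVTKFLFWVHSTRNNSFMPPIFNFRSYYRRMIQVIAGRMFEKKELTGFFSYHYMRMEAKPRYDVLFGPDVEPSWANRVPQHAPMWNSKNYHTN
>SYN0005
LYNWDAKERADFTNYMNRQWNAKMGDLDCYRICLWSKQWMKHQWWWAYKIYGTKKYPCEFSCHTLLEDFQSDYGNIAKTFHWDVPIIGESLIGWYWTAAFWYSGDQTSKTTQPWNTHLESHGIYDYPTRAYWATGITGLSKKVEEMVVFWWLIK
>SYN0006
VRTLRDMATVPKAWKHQCAGDLPDELRCKRMQLSRNMILNIEFYPCQSPLDWASNCVLDITSWDGTPFEYNEVPKIFTPNSNGYVAWSLYILHLIDYTSRQDGAWEWQWPGIDWRSARHRKWSEVWANHSRMSGHMLAAHNYSDRHNSQMDIMLRNQSM
>SYN0007
YSQEYKWGDWEITGDYDRFVCFSKGQTNTHCQAEQRCFPVVRVYQSCTMPIIVIQYVREGHNRIESNRDLATQRYKGLGENLEVNFQKTKRFSFADMMRFRWTEMWGWKAMEAVWKWSSYDPVNVHIHINYLMKGQFKTANLVKNWFLSKWALH
>SYN0008
TEMGFFSKCFVKGAMFYRCVKAMMEHKSAPELCWESIRMVPNCYIPYRENLEQALMADEDTSNGGYRRYADVTFVESVYKSITSGHTPHHPLDFGSDGVVRFMRPRGDNYVQKMQLHAMFFFRLWYSQVTYTENKYNWSVEGAWGDGANKKYLHD
>SYN0009
LDFHGMFMVYCRRHCGREMLWPMHWFENKVHGFGLEIVERYSWNKILITRLYRPNTQSFHFVMPYMEIRYPLQTYNSPERFMDFFYRPWFRRLDTASWQNEQYLRPNSVRFTPFGSDAAQWPIRFDRARHRLWRYRPFFELADRQHWTWLTIAATEKLFSVFARM
>SYN0010
YAVQKDSIKFEGLQVMYTLDTRFANVTCFLLKPNWFWCMELNMYFRDSRHRMENNNSAGPYGFNYKNDWHNNRHRAHVIVARWIQPIIVDDSFHGPSYYLIAQWHWVRLYQPKKNGYTELDLDWETFIIFWEWDIWVNTMFEFSIGGSSRALYPE
>SYN0011
ASTEQAQQWTEPVIDNFYTWPMSKNFTFTMREREPMDPLDHPLMNGNTAPAWMHWLMYHDFFKLPNPEFSLPHTKNDIQLGPINGFLAPPFDYTNDGQPVYTSKRPVFVQVRWWESIHYDIDWQMKISHADIFGLKDTGVLPLPIWVPE
>SYN0012
VYTWAQLSMNFLGTNYDYHILLWDWPYINIEMFDAVTTEEPFESFEVYLIVFERVGGMWWQQRYQAMQERDKYTQVYVIINHTAEKDRFFHAEVTVHYAMHYLSGVNKIINIFASRRAPYEFNSHRKNKLTISNFGVMYVRDDVEIG
>SYN0013
LRYDLWLCGGECTQAIAINRRNQQGIMTNEKITVSYRYIDSAHMQWVAMFRNQLGYWEFDRGLSDGMKFKLYYDQGPFKYDYWDATDHDYDFVYISARFWWFRWHKMPDETHERKRDIHIQVSRDQRGPSFPQPWEHRVFEDLFRLWIG
>SYN0014
YLPHVDQFFRRSVKHPEAGVPIFPNTMMGEFQATKHISVQTEWRKTNTNPYFAHVTKHYQAYTTINPLFGPSLMFHTYNWWKPQQDIEWAGNIWSIAWAFHHGSVNGAHEDHYTYSISPGFEDYGQPTHQMKTWLWWAVQKLWYEDRSRTTHVFFRDWDSWWPVAFPAMKQWH
>SYN0015
DRNPQDMAMFMFGYDHMIHMSGPHNIRMCFFMCSFKITGTMPPTFSGVRAIAEFVADMSSQLVHLAESGAPMEEDHFFPMRDTETVRGLMNMTLSDFALYNWTGSFQEPGGDDEHMRHYVQGRGSEMKDYLVKIGVVPPIEGSPAPQLRTYVLYYW
>SYN0016
QIKLQSQPHESHDVHRLRMQKYPPLDDTDMWFMVFMIFDKSVQRNYWELFFRMNYWMWWVKNERAWNQVMWNFFFWGGMWEHLFKAVMSWVIHTQPNWEEKPGYRHHFFISVNLFMDYHDIMVETQMDMLDFDYAYKSLGIRDIYWEEPIGGAAQ
>SYN0017
FGTIEKHKQQAENWVLRIALWWQWWKVPWDMVNSWIKTIGQDNFQMGMDTWMYVWKRDWQILIRFPFFNMHKAEVFSWHEFVIYSEDDFVHWRMAAFENDINAKWRRNQKPHREARGKKHHGQNWSDIGGHPWASFHHQRNKNSNYTEMMKSDYGDSKGDRTWIYGVMRR
>SYN0018
KNRKEPSTRRKGHALCSHSMMVTMYCYHMPPWGYGAEWRGLPHTMPWYVYFGRDHITKQFKDFRISTIDRSSINLGLMKIMTAFQEMQAPSPPLRADDGQLEKTAASPKRVWHYFVLSFGEGHMSMTQEKWMLDEQVGWFKFVMVPHRIIAAYKND
>SYN0019
STYNHYSMTSNYGWIKAGRVEQAASDECPTMCGGFDMKLQWSEFGAGFQVDDPRRHYFVLVRSWGYGERVMYYQVNTKRYTKKHVPSVFDFGTEFDKQRGHSGDRWMHQNIRVEGMATTNGYGPKVSLAFGAIATVLPYGGEMNTPVYRQGSDASE
>SYN0020
ADPNQAATVMMLRAMILTVFNLTDNRFHEQADYRNYHSTGWSVKDENLHPHRRYEDSTYDWRFQVTWNGHQFWLEHMAQQVYQGQATEIIRLHQAAPLEPDMDVDVAEVNEHRQNPTNMLKIFRRHQGEANRFMYYDVVYQMFLRDQIQYSF
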