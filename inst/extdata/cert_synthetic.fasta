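>CERT_SYNTHETIC_1 synthetic CERT-like protein, 624 aa (randomly generated; NOT a real CERT sequence)
FVAFPCCNSIVATYFNVATSTNDRPYYKETQSDKCLGSYTWSGVMPPNEGATVAKDYREK
TIEDPDFSSVNKEVEALTEIEDWHVVHKITESLGNPSSDTNNFIFVLSKYVRRRKCARKQ
YEGYSKKEGMDLLKVGKREVEIPSCMKIETQTCAQTRMFKNYAEFLLARIKCLSEKDCFQ
LQDSAATKGAALLAPAFASNVVCDLVKKFESGESVTSHLSYGLGFVVAGLSVITMALKYK
SKDEDSMKNVSRLVTPASQEADPEKFGDFKCSKYSAMAAAKRAEEERKGPRVRTSSIAET
VGTQESSRFNSELLKYKCFGETDPFVKPNSAPVDLDKSFHFTIAECGSYISKNTRLTIET
VRPNKSEFENAFQVSIGLTPGEKFNNRFTYGNKNPPTLKRLQFNVQIFRCASGEEDDGVN
FAYVVLAILRYLFINAKGLNSGQTSQYVTIKDQGSTTMLLICSSLESVIQIARCVKGHLS
VNSNTFSTCGLGRLISLMNYTTHDFTVFYWNGTDYSTERAIETKGCFHTRYDARLMSYET
VVLIVSVDDVKYPFGEVRNNITTSYTDWAVVFEDCVNHSLELVLMLFPVNLTHAITDAAV
SLMISQDDLVALHKKIDLGVTRAR
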