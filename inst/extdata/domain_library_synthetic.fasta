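>GAG:gypsy_synthetic
EKKKIITMSSERLPALEGAWQVSAGAVYRSNWLDASIYIARLMEKWLNDLKFDSGTEVQK
YLALKLFCRTKAAGNKFTIEILDEITLGYTSEGIGGNFERSTDILYDQAGLENGSSPKKL
>GAG:copia_synthetic
GNMDAPESRIASLSLARDSLNQWATRMEFAKFDVHFKAFGMHHMFTTAVYKSLNTLYKKA
FNFHPTVSAKSSKYALTWLLTEYGVETFLQMLLMLILKTKLLDRVYKPKDQFSAREDKGS
>AP:gypsy_synthetic
NNRVTVGGSKGEYVDNRERQTANDVATQQPFKMDRTHIRGAWIGPARSKFMKEASKRGTA
LAYLENPYRVIAQEFQESDCPVITQRLLQFTYFGQMDAGY
>AP:copia_synthetic
IFDSGIIENELNVSFIFEDIHTSHNHTAVHEDVIPGVEHGYGQPWGEYQVDEWIMWEPDH
VAIIILESDEIGRKGSEDDTLRQAKVTTCGHMLVTTALVV
>RT:gypsy_synthetic
AELSKSECAPDPSWGPITKSVPQMGPRLDVKGTVEEVRGMVAKSDAQVVKDLIMHPEHMQ
IHIDGMRNARDPRFGSYLETAAKWNEYPYGQEGVLYKCESGFSFGVADGQREIAMLPKDA
QLCIYVAEKSRVDPYVREPPGPSRLYLDVLSLDQHVIHWLLQGWLHPGLNFMTRARGPAL
>RT:copia_synthetic
FRNFVSALLLALDKFRIAEILATSRKDVLNKADAPCARLLVYANLDDREAWIGLESADRE
DASGPDLTIAFDVEVDAIIAMVEYTGAAVNIKIIVHTFAHGIRQPYEVGLLTNCLLPLGY
IIVNEADLKNLDAIQSFRIDVGVSSGFPGLPFVANSSMRIGTVPGVLPVMFALLPEEPFA
>RH:gypsy_synthetic
QPIRLCKAFATEVEMLMRLGESPCGVATYGALIGQMYVEAQAVTSLEFWGALRNAVKQIA
LFVAAVEQLFNFLDKGDLNHDVIRTAGVGATIKVMIDNIPMVTINGCKMRAPRLQEAPKV
WTELLQYALF
>RH:copia_synthetic
FPLDLKYRTRVTANLGNKKVWELQEFFSPQYDEYESSFLQKAFLLPPTANASNLESFIGN
KPIRAEANKSEVSNSDRYDLITHGLGGNTKSDELTDVVVIVANDATVINVDAFCVNQSVI
VRIQLDLAYE
>INT:gypsy_synthetic
KFVGVRAGEERDYVKKDKGFTHKTKQYGMYNPYRCHHPTFDLGEVKIALDASARSIKKVD
EGKGDMRKYMHANPVGMLAFPRAFGQEMRCLDKALEPEPSPASRYIVGKEGPKYTIMEEN
IRREIKASTEAVMTNESLKKTTLLGCHSDV
>INT:copia_synthetic
PDMVRAQQVPGLALKEKIAHPWKTTAEETLPHQGPETKFALYHGPFFVEKLTEDQEVVQE
ERYEWYRMVELYPLLKEGLETARFGQFIPGKDERKWFMALHDDLIGYVQAENHLEPATAN
PPELEASSVFCYGEHSETLISQKFGACTGA
>CHROMO:gypsy_synthetic
VSGYGWYCKYRLDRFGTVETASTTRRLLSFFEEQVVVSALSLSPEAVYAHPLAFLQGDAV
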