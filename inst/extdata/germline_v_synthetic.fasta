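>IGHV3-23*01 chain=heavy segment=V
EVQLLESGGGLVQ.PGGSLRLSCAASGFTF....SSYAMSWVRQAPGKGLEWVSAISGS..GGSTYYADSVKGRFTISRDNSKN.TLYLQMNSLRAEDTAVYYCAK
>IGHV3-11*01 chain=heavy segment=V
QVQLVESGGGLVK.PGGSLRLSCAASGFTF....SDYYMSWIRQAPGKGLEWVSYISSS..GSTIYYADSVKGRFTISRDNAKN.SLYLQMNSLRAEDTAVYYCAR
>IGHV3-7*01 chain=heavy segment=V
EVQLVESGGGLVQ.PGGSLRLSCAASGFTF....SSYWMSWVRQAPGKGLEWVANIKQD..GSEKYYVDSVKGRFTISRDNAKN.SLYLQMNSLRAEDTAVYYCAR
>IGHV1-69*01 chain=heavy segment=V
QVQLVQSGAEVKK.PGSSVKVSCKASGGTF....SSYAISWVRQAPGQGLEWMGGIIPI..FGTANYAQKFQGRVTITADESTS.TAYMELSSLRSEDTAVYYCAR
>IGHV1-2*01 chain=heavy segment=V
QVQLVQSGAEVKK.PGASVKVSCKASGYTF....TGYYMHWVRQAPGQGLEWMGWINPN..SGGTNYAQKFQGRVTMTRDTSIS.TAYMELSRLRSDDTAVYYCAR
>IGHV4-34*01 chain=heavy segment=V
QVQLQQWGAGLLK.PSETLSLTCAVYGGSF....SGYYWSWIRQPPGKGLEWIGEINHS...GSTNYNPSLKSRVTISVDTSKN.QFSLKLSSVTAADTAVYYCAR
>IGHV5-51*01 chain=heavy segment=V
EVQLVQSGAEVKK.PGESLKISCKGSGYSF....TSYWIGWVRQMPGKGLEWMGIIYPG..DSDTRYSPSFQGQVTISADKSIS.TAYLQWSSLKASDTAMYYCAR
>IGKV3-20*01 chain=kappa segment=V
EIVLTQSPGTLSLSPGERATLSCRASQSVS.....SSYLAWYQQKPGQAPRLLIYGA.......SSRATGIPDRFSGSGSGTD...FTLTISRLEPEDFAVYYCQQY
>IGKV1-39*01 chain=kappa segment=V
DIQMTQSPSSLSASVGDRVTITCRASQSI......SSYLNWYQQKPGKAPKLLIYAA.......SSLQSGVPSRFSGSGSGTD...FTLTISSLQPEDFATYYCQQS
>IGKV4-1*01 chain=kappa segment=V
DIVMTQSPDSLAVSLGERATINCKSSQSVLYSSNNKNYLAWYQQKPGQPPKLLIYWA.......STRESGVPDRFSGSGSGTD...FTLTISSLQAEDVAVYYCQQY
>IGKV1-5*01 chain=kappa segment=V
DIQMTQSPSTLSASVGDRVTITCRASQSI......SSWLAWYQQKPGKAPKLLIYKA.......SSLESGVPSRFSGSGSGTE...FTLTISSLQPDDFATYYCQQY
>IGLV1-40*01 chain=lambda segment=V
QSVLTQPPSVSGA.PGQRVTISCTGSSSNIG...AGYDVHWYQQLPGTAPKLLIYGN.......SNRPSGVPDRFSGSKSGTS...ASLAITGLQAEDEADYYCQSY
>IGLV2-14*01 chain=lambda segment=V
QSALTQPASVSGS.PGQSITISCTGTSSDVG...GYNYVSWYQQHPGKAPKLMIYEV.......SKRPSGVSNRFSGSKSGNT...ASLTISGLQAEDEADYYCSSY
>IGLV3-19*01 chain=lambda segment=V
SSELTQDPAVSVA.LGQTVRITCQGDSLR......SYYASWYQQKPGQAPVLVIYGK.......NNRPSGIPDRFSGSSSGNT...ASLTITGAQAEDEADYYCNSR
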