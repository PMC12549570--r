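>P01876 chain=heavy segment=constant isotype=IgA1 synthetic=true
EDRNLYALMQDCVPDLMDLSQWQSSWKTYTGWQAGHKGKSAQPLYGYYAENSYIECTDIKDCYYGVFIDKIWSNAVASPYEDGYMWSFTQPTEWYQLVQHTKIHPCNHRENTYVWIHFHPTQGAYTYNTNEEWNEIHWHPERRFKELVKNMKGINFVMYQNTNHPRICMWALCGEGFFLVPGKSAKLCIRKPTMWQDLTRIGEDSQVRDTPQCFLPLPLVKDGNSEHCCVDHKVGVIWECKAIGDKKWCGLCTTAPHYCQKMPKMLSHPQDIWHMEGEFY
>P0DOX2 chain=heavy segment=constant isotype=IgA2 synthetic=true
ELINMYPLMQDCVPDLMDLMQWQPRWPTYTGWQAEHHGKSQFPLYGYYAENSYIACTDIKDCYYGVFIDKIWSNAVASATVDGYMWSFTQPTSWYQDPHHTKIHPCNHRGNTYVWIHFHPTQGAYTYMTNEEWNEIHWHPERRFKELVKNMKWINFVMCQHTNHYSICMWALCGEGFFLVPGKYASLCITKPTMWQDLTRIGEDSQGRDTPQCFLPLPLVKDGNSEHCCNDHKHDVIWECKAIGDKKWCGECTTAPHYCQKMPKMNSHTQCIWHMEGEFY
>P01857 chain=heavy segment=constant isotype=IgG1 synthetic=true
QCNKQITISKVRTQMTEVCKIFMQAANEYGVGFTLYFKEWFFRGTMKHFWVHTEPHWHYFEKWHRGTEEGCFKFMDHFTQVDFEPCFWFYYNKRARLVLLPVLKNPSVQREHPVKWDANIHDEDDPEKKLAQKQDYWKHSATGNQTDEMGDSWCKDMHIWYQEWSAWSPTWNGGEVFSKPIKANTSHEDEGRCFMFNIVALMMEGTPTTTYPDHTKAAVYICDPHEKYADDKYCAICKRWDVHHTMQVPWIQRIRKWLPKWLMHIWTCVHNENQHQGERIIAPGWWAEFYTFMAIEAKWC
>P0DOX5 chain=heavy segment=constant isotype=IgG1 synthetic=true
QCNKQITISKVRTQMTEVCKIFMQAANEYGVGFTLYFKEYFFRGTMKHFWVHTEPHWHYFEKWHRGTEEGCFKFMDHFTQVDFEPCFWFYYNKRAYLVLLPVLKNPSVQREHPVKWDANIHDEDDPEKKLAQKQDYWKHSATGNQTDEMGDSWCKDMHIWYQEWSAWSPTWNGGEVFSKPIKANTSHEDEGRCFMFNIVALMMEGTPTTTYPDHTKAAVYICDPHEKYADDKYCAICKRWDVHHTMQVPWIQRIRKWLPKWLMHIWTCVHNENQHQGERIIAPGWWAEFYTFMAIEAKWC
>P01859 chain=heavy segment=constant isotype=IgG2 synthetic=true
QCNKQITISKVRTQMTEVCNICMQEANEYGVGCTLYFKEWFYRGTMKHFWKLTEAGWHYEEKAHRGTEEGCFKFMYYFSQVDFEPCFAFSYNKRARLVLLPVLDNPSVQREHKVKWDANIHDCDDPEKKLAGKQDYYKHSAIGACTDEMYDSWCSDMHIWYQEWSAKSPTWNGGEWFTKPYKANVSHEDEGRCFMFNIVTVMMNGTPTTTYPDHQKAWVYICDQQEKYADDKYDAICKRWDDHHTMQVPWIQRIRKWLPKWLEHIWTAVHNGNQHQGEFILAPGWWAELYTFMAIEAKWC
>P01860 chain=heavy segment=constant isotype=IgG3 synthetic=true
QCNKQICISKVRTQMEEVCKICMQAANEYGVGCTCYFKEWFYRGTMKHEWKLTEAGWHYFEKAHRGTEEGCSKFMYYFTQVDFEPCFAFYYNKRARLVLLPVLLNPSVQYEHKVKWDANIHDCDDPEKKLAGKQDYWRHSATGNQMDEMGDSWCSDMHIWYQEWSAHSPTWNGDEWFSKPIKAATSHEDEMRCFMFNIIAIMMIGTMTTTYPDHTKADVYSNWGIEKYADDKYCAICKRWDDHHTMQVPWIQRIRKWLPKWLEHWWHCVHNGNQHQGERIIAPGWWAELYTFMAIEAKWC
>P01861 chain=heavy segment=constant isotype=IgG4 synthetic=true
QCNKQITISKVRTQMTEVCKICMQAANEYNVGCTLYFKEWFYRGTMKHNWKLTEAKWHYFEKAGAGTEVDCKKFLYYFTWVDFEPCFAFYYNKRARLVLTPVLDNPSVQREHKVSWDALIHDCDDPEKKLAGKQDYWKHSATGNQRDEMGDSWCSAMHIWYMEDSAHSCTWNGGEWFSKPIKANTSHEDEGRCFMFNIVAMMMEWTPTTTYPDHTKAWVYICDPHEKYADDKYCAICKRWDVHHTMQVPWIIRDRKWLPKWLEHIWTCVHNGNQHQGERIIEPGWWAELRTFMAIEAKWC
>P01871 chain=heavy segment=constant isotype=IgM synthetic=true
WKQWFYEPTYVILRVCDRNVYCGEVKHAALYFVSMNEVHWCLNKFAMACWIYPRNMQLQKDMARRNVVEKALGDKFMDYFAPPSCHRVIVSMFAEFYPQYIEVLIIMMHFWTATAMHWMQPTGLPGNGSCMDFARTGYSFKSWDGYCKDMKESHNTPRPFSCVCDSMWRTKFSRQNSAEANFQQHEQVMAPRQAKFKRLDQIEFPVMKGQSEQNWLCVYISCTMQMPMWYGCNGIGQGDTPFQGHGADSEVCEKEWQWCMMQVSTHWHHSGMFKKHDGSVRARMTFQVLIPSLLNTFVMVMNICNALRRSMRRKEMPEIK
>P0DOX6 chain=heavy segment=constant isotype=IgM synthetic=true
WKQWFYEPTYVILRVCDRNVYCGEVKHAALYFVSMNEVHWCLNKFAMACWIYPRNMQLQKDMARRNVVEKALGDKFMDYFAPPSCHRVIVSMFAEFYPQYIEVLIIMMHFWTATAMHWMQPTGLPGNGSCMDFARTGYSFKSWDGYCKDMKESHNTPRPFSCVCDSMWRTKFSRQNSAEANFQQHEQVMAPRQAKFKRLDQIEFPVMKGQSERNWLCVYISCTMQMPMWYGCNGIGQGDTPFQGHGADSEVREKEWQWCMMQVSTHWHHSGMFKKHDGSVRARMTFQVLIPSLLNTFVMVMNICNALRRSMRRKEMPEIK
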