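>IGHJ1*01 chain=heavy segment=J
AEYFQHWGQGTLVTVSS
>IGHJ2*01 chain=heavy segment=J
YWYFDLWGRGTLVTVSS
>IGHJ3*01 chain=heavy segment=J
DAFDVWGQGTMVTVSS
>IGHJ4*01 chain=heavy segment=J
YFDYWGQGTLVTVSS
>IGHJ5*01 chain=heavy segment=J
NWFDSWGQGTLVTVSS
>IGHJ6*01 chain=heavy segment=J
YYYYYGMDVWGQGTTVTVSS
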