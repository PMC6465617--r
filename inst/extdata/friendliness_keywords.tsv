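keyword	class
milk	friendly
cheese	friendly
yogurt	friendly
yoghurt	friendly
beer	friendly
human gut	friendly
food	friendly
dairy	friendly
patient	unfriendly
specimen	unfriendly
soil	unfriendly
blood	unfriendly
saliva	unfriendly
silage	unfriendly
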