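>lys_frag synthetic demo fragment
KVFGRCELAAAMKRHGLDNYRGYSLGNWVCAAKFESNFNTQATNRNTDGSTDYGILQINSRW
>acidic_pep synthetic demo peptide
ACDEEDSGGDYK
>basic_pep synthetic demo peptide
GKRHKARSLKG
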