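drug_name,drug_id
teriflunomide,D001
insuline glargine,D002
zolpidem,D003
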