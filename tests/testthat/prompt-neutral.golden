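Rephrase the following user-facing question in a neutral manner, as defined below. Do not alter the meaning or structure of the item.
Style definition: concise, factual, and emotionally neutral
Question: 'I have a problem and I think I should work on it.'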