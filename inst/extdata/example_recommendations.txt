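People of any age who are African Americans should further reduce sodium intake to 300 mg per day. Babies need protein about 10 g a day. 1 teaspoon of table salt contains 2300 mg of sodium. The body of a 76 kg man contains about 12 kg of protein. Your hat looks very nice.
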