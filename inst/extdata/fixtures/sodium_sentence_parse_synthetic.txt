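(S
  (NP
    (NP (NNS People))
    (PP (IN of) (NP (DT any) (NN age)))
    (SBAR (WHNP (WP who))
      (S (VP (VBP are) (NP (JJ African) (NNPS Americans))))))
  (VP (MD should)
    (ADVP (RBR further))
    (VP (VB reduce)
      (NP (NN sodium) (NN intake))
      (PP (TO to)
        (NP (NP (CD 300) (NN mg)) (PP (IN per) (NP (NN day)))))))
  (. .))
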