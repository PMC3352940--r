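#NEXUS
[ Template for a user-supplied transcription of the published coelurosaurian
  character-taxon matrix (>= 307 discrete characters; the supplementary
  matrix is distributed as a word-processor document and must be transcribed
  to this plain-text form once, by hand or with external tooling).
  Save the completed transcription as coelurosauria_matrix.nex next to this
  template, or pass its path to run_analysis()/parse_matrix() directly.
  Polymorphic cells use {..}; ? = missing; - = inapplicable. ]
BEGIN DATA;
  DIMENSIONS NTAX=0 NCHAR=307;
  FORMAT SYMBOLS="0 1 2 3 4 5" MISSING=? GAP=-;
  MATRIX
  ;
END;
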