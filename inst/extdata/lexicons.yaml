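# Qualification cue lexicon and section-title lexicon (starter content,
# fully overridable). Cue phrases are written in normalized form (lowercase,
# no diacritics); multi-word cues are matched as token subsequences. French
# cues plus a small set of English demo cues.

cues:
  negation_preceding:
    - "pas de"
    - "pas d'"
    - "sans"
    - "absence de"
    - "absence d'"
    - "aucun"
    - "aucune"
    - "jamais de"
    - "ni"
    - "no"
    - "negatif pour"
    - "on elimine"
  negation_following:
    - "est exclu"
    - "est exclue"
    - "non retrouve"
    - "non retrouvee"
    - "est ecarte"
    - "est ecartee"
    - "ruled out"
  hypothesis:
    - "suspicion de"
    - "suspicion d'"
    - "suspecte"
    - "possible"
    - "probable"
    - "eventuel"
    - "eventuelle"
    - "evocateur de"
    - "a eliminer"
    - "doute sur"
    - "may have"
  family:
    - "pere"
    - "mere"
    - "frere"
    - "soeur"
    - "grand-pere"
    - "grand-mere"
    - "oncle"
    - "tante"
    - "familial"
    - "familiale"
    - "familiaux"
    - "father"
    - "mother"
  scope_window_tokens:
    negation: 5
    hypothesis: 6
    family: 8
  scope_terminators:
    - "."
    - ";"
    - ":"
    - "!"
    - "?"
    - "mais"
    - "but"
    - "cependant"
    - "toutefois"

# Section titles are matched at line starts, followed by a colon.
sections:
  - pattern: "antecedents familiaux"
    relevance: family_history
  - pattern: "histoire familiale"
    relevance: family_history
  - pattern: "antecedents personnels"
    relevance: relevant
  - pattern: "antecedents"
    relevance: relevant
  - pattern: "motif d'hospitalisation"
    relevance: relevant
  - pattern: "motif de consultation"
    relevance: relevant
  - pattern: "histoire de la maladie"
    relevance: relevant
  - pattern: "examen clinique"
    relevance: relevant
  - pattern: "mode de vie"
    relevance: relevant
  - pattern: "biologie"
    relevance: relevant
  - pattern: "traitement de sortie"
    relevance: relevant
  - pattern: "traitement"
    relevance: relevant
  - pattern: "conclusion"
    relevance: relevant
  - pattern: "signature"
    relevance: irrelevant
  - pattern: "destinataires"
    relevance: irrelevant
  - pattern: "references du courrier"
    relevance: irrelevant
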