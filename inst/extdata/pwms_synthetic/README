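Synthetic position frequency matrices for the five pluripotency
transcription factors (Esrrb, Klf4, Sox2, Oct4, Nanog), in JASPAR bracket
format. These are hand-constructed stand-ins with realistic consensus
sequences and information-content profiles, NOT curated database matrices;
they exist so that motif scanning, module detection and mutagenesis design
can be exercised and tested without external downloads.
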