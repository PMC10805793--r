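#!/usr/bin/env Rscript
# Build the two constrained letter-string stimulus sets:
#   experiment 1 — vowel detection: strings with exactly one vowel vs.
#     all-consonant strings (each carrying a visually vowel-like consonant);
#   experiment 2 — pronounceability: template-legal pseudowords vs.
#     one-vowel strings violating the onset/vowel/coda rule, matched on
#     starting letter.
# The full sets used in the task have 1,651 (exp 1) and 790 (exp 2) strings
# per category.

suppressPackageStartupMessages(library(dualcap))
dir.create("results", showWarnings = FALSE)

exp1 <- gen_stimuli_exp1(1651, seed = 11)
write_stimuli(exp1, "results/stimuli_exp1.csv")
message("experiment 1: ", nrow(exp1), " strings (",
        sum(exp1$category == "present"), " vowel-present, ",
        sum(exp1$category == "absent"), " vowel-absent)")

exp2 <- gen_stimuli_exp2(790, seed = 12)
write_stimuli(exp2, "results/stimuli_exp2.csv")
message("experiment 2: ", nrow(exp2), " strings, ",
        sum(is_pronounceable(exp2$text)), " pronounceable; start letters ",
        "matched: ",
        all(table(substr(exp2$text, 1, 1), exp2$category)[, 1] ==
              table(substr(exp2$text, 1, 1), exp2$category)[, 2]))
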