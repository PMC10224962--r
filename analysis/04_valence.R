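#!/usr/bin/env Rscript
# Stage 4 — vocal expression of contextual valence.
#
# Restricts the corpus to calls of clear positive/negative valence
# (clucking vs terror + handling), tests the multivariate effect of valence
# on the first five PC scores (MANOVA, Pillai's trace, call type as control
# fixed factor), then fits the eight per-parameter linear models whose
# intercept is the negative-valence mean and whose effect is the
# positive-minus-negative difference.

library(aukcalls)
library(jsonlite)

tab <- read.csv("results/feature_table.csv", stringsAsFactors = FALSE)
model <- fit_pca(tab)

vs <- valence_subset(tab)
cat("Inferential subset:", nrow(vs), "calls (",
    paste(names(table(vs$call_type)), table(vs$call_type), collapse = ", "),
    ")\n")

idx <- match(vs$call_id, sort(tab$call_id))
pcs <- model$scores[idx, 1:5, drop = FALSE]
man <- manova_on_pcs(pcs, vs$valence, vs$call_type)
cat(sprintf("MANOVA (Pillai): statistic %.3f, F %.2f, p %s\n",
            man$statistic, man$F, format.pval(man$p_value)))
write_json(list(statistic = man$statistic, F = man$F, df = man$df,
                p_value = man$p_value, aliased = man$aliased,
                n_obs = nrow(vs)),
           "results/manova.json", auto_unbox = TRUE, digits = NA,
           pretty = TRUE)

vm <- fit_valence_models(vs)
write.csv(as.data.frame(vm), "results/valence_models.csv", row.names = FALSE)
cat("Valence linear models (n =", unique(vm$n_obs), "):\n")
print(data.frame(parameter = vm$parameter,
                 negative_intercept = round(vm$intercept_estimate, 2),
                 positive_effect = round(vm$effect_estimate, 2),
                 p = signif(vm$effect_p, 3), R2 = round(vm$r2, 3)))
cat("Wrote results/manova.json, results/valence_models.csv\n")
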