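#!/usr/bin/env Rscript

# Stage 4: output elasticities and returns to scale.
#
# Evaluates the translog fit's input elasticities at the sample mean of the
# log inputs (the geometric mean of levels), sums them into the scale
# elasticity and classifies returns to scale; also reports the sum with
# doctors held constant, and the Cobb-Douglas slopes for comparison.

library(hospfrontier)

panel <- load_panel("results/panel.csv")

design <- build_design(panel, frontier_spec("translog"))
fit <- fit_frontier(design)
stopifnot(fit$converged)
tab <- input_elasticities(fit, design = design)
print(tab)
write_elasticities(tab, "results/elasticities.csv")

rts <- scale_elasticity(tab)
no_doc <- scale_elasticity(tab, exclude = "doctors")
cat(sprintf("\nScale elasticity: %.3f (%s returns to scale)\n",
            rts$scale_elasticity, rts$rts_class))
cat(sprintf("Holding doctors constant: %.3f\n", no_doc$scale_elasticity))

cd <- fit_frontier(build_design(panel, frontier_spec("cobb_douglas")))
cat("\nCobb-Douglas slopes (point-free elasticities):\n")
print(round(input_elasticities(cd)$elasticity, 3))
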