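#!/usr/bin/env Rscript
# Step 3 — what can a 3-locus panel actually detect?
#
# The diagnosis rule is only as good as the panel behind it: a first
# backcross (BC1) is heterozygous at each diagnostic locus with probability
# 1/2, so with L = 3 loci it masquerades as an F1 (all het) or even as a
# pure fish (all hom) 1/8 of the time each. This step computes the exact
# category probabilities for the informative crosses, cross-checks them by
# Monte Carlo, and traces post-F1 detection power as the panel grows.

suppressPackageStartupMessages(library(hybriddiag))
dir.create("results", showWarnings = FALSE)

panel <- default_catfish_panel()
F1 <- cross(leaf("Pret"), leaf("Pcor"))
crosses <- list(
  F1 = F1,
  F2 = cross(F1, F1),
  BC1 = cross(F1, leaf("Pret")),
  BC2 = cross(cross(F1, leaf("Pret")), leaf("Pret")),
  F1xBC1 = cross(F1, cross(F1, leaf("Pret")))
)

n_mc <- 10000
rows <- list()
for (nm in names(crosses)) {
  ex <- category_distribution(crosses[[nm]], panel)
  mc <- mc_category_distribution(crosses[[nm]], panel, n_reps = n_mc,
                                 seed = 20260926)
  rows[[nm]] <- data.frame(
    cross = nm, pedigree = format(crosses[[nm]]),
    p_pure_exact = sum(ex$p_pure), p_f1_exact = ex$p_f1,
    p_postf1_exact = ex$p_postf1,
    p_pure_mc = sum(mc$p_pure), p_f1_mc = mc$p_f1,
    p_postf1_mc = mc$p_postf1)
}
power_tbl <- do.call(rbind, rows)
write.csv(power_tbl, "results/category_power.csv", row.names = FALSE)

cat("Category probabilities under the 3-locus panel (exact | MC, n =",
    n_mc, "):\n")
print(power_tbl, row.names = FALSE, digits = 4)

bc1_curve <- detection_curve(crosses$BC1, panel, L_values = 1:10)
f2_curve <- detection_curve(crosses$F2, panel, L_values = 1:10)
curve <- rbind(cbind(cross = "BC1", bc1_curve),
               cbind(cross = "F2", f2_curve))
write.csv(curve, "results/detection_curve.csv", row.names = FALSE)

cat("\nPost-F1 detection power by panel size L (BC1):\n")
print(bc1_curve[, c("L", "p_postf1")], row.names = FALSE)
cat("\nWith the 3 published loci a BC1 escapes detection 25% of the time;\n")
cat("8 loci push that below 1%. A single locus detects nothing: the\n")
cat("combined hom+het pattern needs at least two loci to exist.\n")
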