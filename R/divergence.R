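#' Courtship distance vs genetic distance across population pairs
#'
#' Joins the two divergence surfaces at the population-pair level: for every
#' unordered pair of populations shared by the two matrices, the mean
#' (symmetrized) inter-individual courtship KL divergence with its standard
#' error, and the mean inter-individual Kosman genetic distance. The
#' individuals behind the two matrices need not be the same animals -- only
#' their populations must map onto each other. The relationship is
#' summarized by an ordinary least-squares fit of courtship mean on genetic
#' mean (R^2), with a Spearman rank correlation alongside; with fewer than
#' 10 population pairs the R^2 carries an explicit small-sample caveat flag.
#'
#' @param courtship individual courtship distance matrix from
#'   [pairwise_courtship_distances()] (asymmetric is fine; it is symmetrized
#'   by averaging the two directions).
#' @param genetic individual Kosman distance matrix.
#' @param courtship_pops named vector: courtship individual -> population.
#' @param genetic_pops named vector: genetic individual -> population.
#' @return object of class `courtship_genetic_fit`: list with `records`
#'   (data.frame `pop_a`, `pop_b`, `mean_kl`, `se_kl`, `mean_kosman`),
#'   `r_squared`, `spearman_rho`, `coefficients`, `small_n`.
#' @export
courtship_vs_genetic <- function(courtship, genetic,
                                 courtship_pops, genetic_pops) {
  cs <- (courtship + t(courtship)) / 2
  kl <- population_divergence_summary(cs, courtship_pops)
  ks <- population_pair_means(genetic, genetic_pops)
  kl <- kl[kl$pop_a != kl$pop_b, ]
  ks <- ks[ks$pop_a != ks$pop_b, ]
  key <- function(d) paste(pmin(d$pop_a, d$pop_b), pmax(d$pop_a, d$pop_b))
  m <- match(key(kl), key(ks))
  keep <- !is.na(m)
  rec <- data.frame(pop_a = kl$pop_a[keep], pop_b = kl$pop_b[keep],
                    mean_kl = kl$mean_kl[keep], se_kl = kl$se_kl[keep],
                    mean_kosman = ks$mean[m[keep]],
                    stringsAsFactors = FALSE)
  if (nrow(rec) < 2) stop("need at least 2 shared population pairs")
  fit <- stats::lm(mean_kl ~ mean_kosman, data = rec)
  # a flat response explains nothing: define R^2 = 0 rather than 0/0
  # perfect fits are legitimate here (e.g. 2 pairs): silence summary.lm
  r2 <- if (stats::var(rec$mean_kl) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  rho <- suppressWarnings(
    stats::cor(rec$mean_kl, rec$mean_kosman, method = "spearman"))
  structure(list(records = rec, r_squared = r2, spearman_rho = rho,
                 coefficients = stats::coef(fit),
                 small_n = nrow(rec) < 10),
            class = "courtship_genetic_fit")
}

#' @export
print.courtship_genetic_fit <- function(x, ...) {
  cat("Courtship vs genetic distance over", nrow(x$records),
      "population pairs\n")
  print(x$records, row.names = FALSE, digits = 4)
  cat(sprintf("OLS R^2 = %.3f%s; Spearman rho = %.3f\n", x$r_squared,
              if (x$small_n) " (small number of pairs; interpret with caution)" else "",
              x$spearman_rho))
  invisible(x)
}

#' @export
plot.courtship_genetic_fit <- function(x, ...) {
  rec <- x$records
  ylim <- range(c(rec$mean_kl - rec$se_kl, rec$mean_kl + rec$se_kl),
                na.rm = TRUE)
  plot(rec$mean_kosman, rec$mean_kl, pch = 19, ylim = ylim,
       xlab = "Mean inter-individual Kosman distance",
       ylab = "Mean inter-individual KL divergence", ...)
  graphics::segments(rec$mean_kosman, rec$mean_kl - rec$se_kl,
                     rec$mean_kosman, rec$mean_kl + rec$se_kl)
  graphics::abline(stats::lm(mean_kl ~ mean_kosman, data = rec), lty = 2)
  graphics::text(rec$mean_kosman, rec$mean_kl,
                 paste(rec$pop_a, rec$pop_b, sep = "-"), pos = 3, cex = 0.8)
  invisible(x)
}

#' Write the population-pair records and fit summary
#'
#' @param x a `courtship_genetic_fit`.
#' @param csv_path output CSV for the per-pair records.
#' @param json_path optional output JSON for the fit summary.
#' @export
write_divergence_link <- function(x, csv_path, json_path = NULL) {
  utils::write.csv(x$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(r_squared = x$r_squared, spearman_rho = x$spearman_rho,
           intercept = unname(x$coefficients[1]),
           slope = unname(x$coefficients[2]),
           n_pairs = nrow(x$records), small_n = x$small_n),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
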