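#' Paired agreement statistics between two scanners
#'
#' For matched per-breast measurements from a "former" and a "latter"
#' scanner, computes the signed mean difference (former - latter), a paired
#' two-tailed t-test on the differences, Pearson's correlation of the
#' pairs, and Bland-Altman bias with 95% limits of agreement
#' (bias +/- 1.96 x sample SD of the differences).
#'
#' Zero-variance differences make the t-test degenerate: the statistic is
#' reported as 0 (or +/-Inf for a constant non-zero offset) with a flagged
#' `NA` p-value. Zero variance in either input flags the correlation `NA`.
#'
#' @param former,latter Equal-length numeric vectors (n >= 3), matched by
#'   (subject, side).
#' @param former_name,latter_name Scanner labels carried into the report.
#' @return Object of class `agreement_report`.
#' @examples
#' paired_stats(c(52, 56, 60), c(50, 52, 54))
#' @export
paired_stats <- function(former, latter, former_name = "former",
                         latter_name = "latter") {
  if (length(former) != length(latter))
    stop("former and latter must be matched sequences of equal length")
  n <- length(former)
  if (n < 3) stop("at least 3 pairs are required")
  d <- former - latter
  mean_d <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_stat <- if (mean_d == 0) 0 else sign(mean_d) * Inf
    p_value <- NA_real_
    zero_var_diff <- TRUE
  } else {
    t_stat <- mean_d / (sd_d / sqrt(n))
    p_value <- 2 * stats::pt(-abs(t_stat), df = n - 1)
    zero_var_diff <- FALSE
  }
  r <- if (stats::sd(former) == 0 || stats::sd(latter) == 0) NA_real_
       else stats::cor(former, latter)
  loa <- mean_d + c(-1, 1) * 1.96 * sd_d
  structure(list(former = former_name, latter = latter_name, n = n,
                 mean_delta = mean_d, t_stat = t_stat, p_value = p_value,
                 pearson_r = r, ba_bias = mean_d,
                 ba_loa_low = loa[1], ba_loa_high = loa[2],
                 zero_variance = zero_var_diff),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement %s vs %s>  n=%d\n", x$former, x$latter, x$n))
  cat(sprintf("  mean delta %+.3f pp; t=%.4f, p=%s; r=%s\n",
              x$mean_delta, x$t_stat,
              ifelse(is.na(x$p_value), "NA (zero-variance)",
                     sprintf("%.4g", x$p_value)),
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.4f", x$pearson_r))))
  cat(sprintf("  Bland-Altman bias %+.3f pp, LoA [%.3f, %.3f]\n",
              x$ba_bias, x$ba_loa_low, x$ba_loa_high))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(former = x$former, latter = x$latter, n = x$n,
             mean_delta = x$mean_delta, t_stat = x$t_stat,
             p_value = x$p_value, pearson_r = x$pearson_r,
             ba_bias = x$ba_bias, ba_loa_low = x$ba_loa_low,
             ba_loa_high = x$ba_loa_high, stringsAsFactors = FALSE)
}

#' Ordinary least-squares calibration between two scanners
#'
#' Fits target = slope * source + intercept by OLS on matched pairs.
#'
#' @param source,target Matched numeric vectors; `source` needs at least
#'   two distinct values.
#' @param source_scanner,target_scanner Labels.
#' @param fold Optional held-out unit id (used by [loo_calibrate()]).
#' @return Object of class `calibration_model` with `slope`, `intercept`,
#'   `n_train`, `fold`, `source_scanner`, `target_scanner`,
#'   `train_keys` (audit trail of the training units).
#' @export
fit_calibration <- function(source, target, source_scanner = "source",
                            target_scanner = "target", fold = NA_character_) {
  if (length(source) != length(target))
    stop("source and target must be matched sequences")
  if (length(unique(source)) < 2)
    stop("source values are constant: calibration line is unidentifiable")
  fit <- stats::lm(target ~ source)
  co <- stats::coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 n_train = length(source), fold = fold,
                 source_scanner = source_scanner,
                 target_scanner = target_scanner,
                 train_keys = character(0)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration %s -> %s>  target = %.4f x source %+.4f (n=%d%s)\n",
              x$source_scanner, x$target_scanner, x$slope, x$intercept,
              x$n_train,
              if (!is.na(x$fold)) paste0(", held out ", x$fold) else ""))
  invisible(x)
}

# Merge two density tables on (subject_id, side); errors if keys mismatch.
match_density_tables <- function(records_source, records_target) {
  key <- function(df) paste(df$subject_id, df$side, sep = "|")
  ks <- key(records_source); kt <- key(records_target)
  if (anyDuplicated(ks) || anyDuplicated(kt))
    stop("duplicate (subject, side) keys in a density table")
  if (!setequal(ks, kt))
    stop("source and target tables must cover the same (subject, side) keys")
  records_target <- records_target[match(ks, kt), ]
  data.frame(subject_id = records_source$subject_id,
             side = records_source$side,
             source = records_source$magdensity_percent,
             target = records_target$magdensity_percent,
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated linear calibration
#'
#' For every held-out unit (a subject by default, so both breasts of one
#' woman leave the training set together), fits the OLS calibration on all
#' remaining matched pairs and applies it to the held-out source values.
#' No unit's own data enters the model that calibrates it.
#'
#' @param records_source,records_target Density tables (data frames with
#'   columns `subject_id`, `side`, `scanner`, `magdensity_percent`)
#'   covering the same (subject, side) keys.
#' @param unit Fold unit: `"subject"` (default) or `"breast"`.
#' @return Calibrated copy of `records_source` with columns
#'   `magdensity_percent` (calibrated values) and `fold`; the per-fold
#'   models are attached as attribute `models`.
#' @export
loo_calibrate <- function(records_source, records_target,
                          unit = c("subject", "breast")) {
  unit <- match.arg(unit)
  pairs <- match_density_tables(records_source, records_target)
  pairs$unit_id <- if (unit == "subject") pairs$subject_id
                   else paste(pairs$subject_id, pairs$side, sep = "|")
  units <- unique(pairs$unit_id)
  if (length(units) < 3)
    stop("at least 3 folds (distinct units) are required")

  out <- records_source
  out$fold <- NA_character_
  calibrated <- numeric(nrow(pairs))
  models <- vector("list", length(units))
  names(models) <- units
  for (u in units) {
    hold <- pairs$unit_id == u
    m <- fit_calibration(pairs$source[!hold], pairs$target[!hold],
                         source_scanner = records_source$scanner[1],
                         target_scanner = records_target$scanner[1],
                         fold = u)
    m$train_keys <- unique(pairs$unit_id[!hold])
    models[[u]] <- m
    calibrated[hold] <- m$slope * pairs$source[hold] + m$intercept
    out$fold[hold] <- u
  }
  out$magdensity_percent <- calibrated
  attr(out, "models") <- models
  out
}

#' Cross-scanner agreement report for a three-scanner study
#'
#' Splits a density table by scanner and emits paired agreement reports
#' for mmr-vs-prisma, mmr-vs-signa and prisma-vs-signa before calibration,
#' then leave-one-out calibrates the signa values against mmr (the two 3T
#' scanners agree, so a single calibration pathway suffices) and reports
#' mmr-vs-calibrated-signa and prisma-vs-calibrated-signa.
#'
#' @param density_table Data frame with columns `subject_id`, `side`,
#'   `scanner`, `magdensity_percent` covering scanners `"prisma"`,
#'   `"mmr"`, `"signa"` on matched keys.
#' @param unit Fold unit for [loo_calibrate()].
#' @return List of class `study_report` with elements `pre` and `post`
#'   (named lists of `agreement_report`s), `calibrated` (the calibrated
#'   signa table) and `summary` (all reports as one data frame).
#' @export
study_report <- function(density_table, unit = c("subject", "breast")) {
  unit <- match.arg(unit)
  needed <- c("prisma", "mmr", "signa")
  have <- unique(density_table$scanner)
  if (!all(needed %in% have))
    stop("density table must contain scanners: ",
         paste(setdiff(needed, have), collapse = ", "), " missing")
  tab <- function(sc) {
    t <- density_table[density_table$scanner == sc, ]
    t[order(t$subject_id, t$side), ]
  }
  prisma <- tab("prisma"); mmr <- tab("mmr"); signa <- tab("signa")
  aligned <- function(a, b) {
    p <- match_density_tables(a, b)
    paired_stats(p$source, p$target, a$scanner[1], b$scanner[1])
  }
  pre <- list(
    mmr_vs_prisma = aligned(mmr, prisma),
    mmr_vs_signa = aligned(mmr, signa),
    prisma_vs_signa = aligned(prisma, signa))

  signa_cal <- loo_calibrate(signa, mmr, unit = unit)
  signa_cal$scanner <- "signa_calibrated"
  post <- list(
    mmr_vs_signa_calibrated = aligned(mmr, signa_cal),
    prisma_vs_signa_calibrated = aligned(prisma, signa_cal))

  summary <- do.call(rbind, lapply(c(pre, post), as.data.frame))
  summary <- cbind(comparison = names(c(pre, post)), summary,
                   stage = c(rep("pre", 3), rep("post", 2)))
  rownames(summary) <- NULL
  structure(list(pre = pre, post = post, calibrated = signa_cal,
                 summary = summary),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Cross-scanner MagDensity agreement\n")
  cat("-- before calibration --\n")
  for (r in x$pre) print(r)
  cat("-- after leave-one-out calibration of signa against mmr --\n")
  for (r in x$post) print(r)
  invisible(x)
}
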