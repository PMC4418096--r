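#' Tags-per-million normalization
#'
#' `TPM = count / library_total * 1e6`. Detection is recorded explicitly:
#' a zero count is "not detected", distinct from a detected-but-small value.
#'
#' @param counts Long tibble with `feature_name`, `stage`, `count`.
#' @param library_totals Named numeric vector of total reads per stage.
#' @return Long tibble `feature_name`, `stage`, `count`, `tpm`, `detected`.
#' @examples
#' counts <- tibble::tibble(feature_name = "miR-x", stage = "AM", count = 10)
#' compute_tpm(counts, c(AM = 1e6))
#' @export
compute_tpm <- function(counts, library_totals) {
  tot <- library_totals[counts$stage]
  if (anyNA(tot) || any(tot <= 0)) {
    stop("every stage needs a positive library total", call. = FALSE)
  }
  counts$tpm <- counts$count / unname(tot) * 1e6
  counts$detected <- counts$count > 0
  counts
}

#' Conditional binomial exact test for a two-library count contrast
#'
#' Without replicates, equal relative abundance of a feature in two
#' libraries is tested conditionally on the summed count: under the null,
#' `count_a | (count_a + count_b) ~ Binomial(n, total_a / (total_a +
#' total_b))`. The two-sided p-value sums all outcomes at most as probable
#' as the observed one (the minimum-likelihood rule). Vectorized over
#' counts.
#'
#' @param count_a,count_b Feature counts in the two libraries.
#' @param total_a,total_b Library totals.
#' @return Two-sided p-values in (0, 1].
#' @export
exact_count_test <- function(count_a, total_a, count_b, total_b) {
  stopifnot(all(total_a > 0), all(total_b > 0),
            all(count_a >= 0), all(count_b >= 0))
  n <- count_a + count_b
  pr <- total_a / (total_a + total_b)
  k <- length(n)
  pr <- rep_len(pr, k)
  out <- numeric(k)
  for (i in seq_len(k)) {
    if (n[i] == 0) { out[i] <- 1; next }
    d <- dbinom(0:n[i], n[i], pr[i])
    ## relative tolerance guards ties against floating-point noise
    out[i] <- min(1, sum(d[d <= d[count_a[i] + 1] * (1 + 1e-7)]))
  }
  out
}

#' Apply the three-criterion regulation filter
#'
#' A feature is called regulated in a contrast when all three hold: fold
#' change > `fc_threshold` in either direction (strict), p-value <=
#' `p_threshold`, and the larger of the two stage TPMs > `tpm_threshold`.
#' Using the maximum of the two stages for the TPM gate keeps off-to-on
#' switches (TPM 0 in one stage) callable.
#'
#' @param fold_change Ratio (stage b over stage a), pseudocounted upstream.
#' @param p_value Exact-test p-value.
#' @param max_tpm Maximum TPM of the two compared stages.
#' @param fc_threshold,p_threshold,tpm_threshold Filter constants
#'   (defaults 2, 0.05, 10).
#' @return Tibble with `fold_change`, `p_value`, `max_tpm`, `passes`,
#'   `direction` (`"up"`/`"down"` in stage b relative to a).
#' @export
de_filter <- function(fold_change, p_value, max_tpm, fc_threshold = 2,
                      p_threshold = 0.05, tpm_threshold = 10) {
  passes <- (fold_change > fc_threshold | fold_change < 1 / fc_threshold) &
    p_value <= p_threshold & max_tpm > tpm_threshold
  tibble::tibble(fold_change = fold_change, p_value = p_value,
                 max_tpm = max_tpm, passes = passes,
                 direction = ifelse(fold_change >= 1, "up", "down"))
}

#' Run two-library contrasts over a count table
#'
#' For each contrast `a:b`, computes per-feature TPMs, the pseudocounted
#' fold change (b over a), the conditional binomial exact p-value on the
#' raw counts, and the three-criterion filter. Returns a `mir_de` object
#' with [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param counts Long count tibble (`feature_name`, `stage`, `count`).
#' @param library_totals Named vector of per-stage totals.
#' @param contrasts Character vector like `c("AM:AF", "LM:PM")` (fold change
#'   is second over first) or a two-column tibble `stage_a`, `stage_b`.
#' @param pseudo_tpm Pseudocount added to both TPMs in the ratio
#'   (default 0.1).
#' @param fc_threshold,p_threshold,tpm_threshold Filter constants.
#' @param adjust Optional multiple-testing correction across features within
#'   a contrast, e.g. `"BH"`; default `"none"`, matching the plain p-value
#'   criterion.
#' @return A `mir_de` object: list with `results` (long tibble) and the
#'   thresholds used.
#' @export
run_contrasts <- function(counts, library_totals, contrasts,
                          pseudo_tpm = 0.1, fc_threshold = 2,
                          p_threshold = 0.05, tpm_threshold = 10,
                          adjust = "none") {
  if (is.character(contrasts)) {
    parts <- strsplit(contrasts, ":", fixed = TRUE)
    contrasts <- tibble::tibble(
      stage_a = vapply(parts, `[`, character(1), 1),
      stage_b = vapply(parts, `[`, character(1), 2)
    )
  }
  stages_used <- unique(c(contrasts$stage_a, contrasts$stage_b))
  unknown <- setdiff(stages_used, names(library_totals))
  if (length(unknown) > 0) {
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ## complete the count grid so absent features score count 0
  grid <- tidyr::expand_grid(feature_name = unique(counts$feature_name),
                             stage = stages_used)
  cts <- dplyr::left_join(grid, counts[c("feature_name", "stage", "count")],
                          by = c("feature_name", "stage")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0))
  tpm <- compute_tpm(cts, library_totals)
  res <- purrr::pmap(contrasts, function(stage_a, stage_b) {
    a <- dplyr::filter(tpm, .data$stage == stage_a)
    b <- dplyr::filter(tpm, .data$stage == stage_b)
    b <- b[match(a$feature_name, b$feature_name), ]
    p <- exact_count_test(a$count, library_totals[[stage_a]],
                          b$count, library_totals[[stage_b]])
    p <- stats::p.adjust(p, method = adjust)
    fc <- (b$tpm + pseudo_tpm) / (a$tpm + pseudo_tpm)
    flt <- de_filter(fc, p, pmax(a$tpm, b$tpm), fc_threshold, p_threshold,
                     tpm_threshold)
    dplyr::bind_cols(
      tibble::tibble(feature_name = a$feature_name, stage_a = stage_a,
                     stage_b = stage_b, count_a = a$count, count_b = b$count,
                     tpm_a = a$tpm, tpm_b = b$tpm),
      flt
    )
  }) |> dplyr::bind_rows()
  structure(
    list(results = res, tpm = tpm,
         thresholds = list(fc = fc_threshold, p = p_threshold,
                           tpm = tpm_threshold, pseudo_tpm = pseudo_tpm,
                           adjust = adjust)),
    class = "mir_de"
  )
}

#' @export
print.mir_de <- function(x, ...) {
  n <- sum(x$results$passes)
  cat("<mir_de> ", dplyr::n_distinct(x$results$feature_name), " features, ",
      dplyr::n_distinct(paste(x$results$stage_a, x$results$stage_b)),
      " contrast(s), ", n, " regulated calls\n", sep = "")
  invisible(x)
}

#' @rdname run_contrasts
#' @param x A `mir_de` object.
#' @param ... Unused.
#' @export
tidy.mir_de <- function(x, ...) x$results

#' @rdname run_contrasts
#' @export
glance.mir_de <- function(x, ...) {
  x$results |>
    dplyr::summarise(
      n_features = dplyr::n(),
      n_regulated = sum(.data$passes),
      n_up = sum(.data$passes & .data$direction == "up"),
      n_down = sum(.data$passes & .data$direction == "down"),
      .by = c("stage_a", "stage_b")
    )
}

#' Heat-map of expression across stages
#'
#' Tile plot of log10(TPM + pseudocount) per feature and stage, the usual
#' overview of stage-resolved miRNA expression.
#'
#' @param object A `mir_de` object.
#' @param ... Unused.
#' @export
autoplot.mir_de <- function(object, ...) {
  dat <- object$tpm |>
    dplyr::mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$feature_name,
                                    fill = log10(.data$tpm + 0.1))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(TPM + 0.1)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
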