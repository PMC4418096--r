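#' Load the curated published-table fixtures
#'
#' Three tables transcribed from the published study ship with the package:
#' the 111-row known-miRNA stage-expression table (TPM across LM, LF, PM,
#' PF, AM, AF with an explicit detection mask), the 14-row novel
#' mature/precursor table, and the 29-row degradome target table with
#' per-condition categories. Cells whose column placement could not be read
#' unambiguously off the printed layout carry a curation flag (`inferred`,
#' `truncated`, `position_unresolved`) and are never silently guessed.
#'
#' @param path Directory containing the fixture TSVs; defaults to the
#'   package's `extdata`.
#' @return List of tibbles `table2`, `table3`, `table5`, validated for
#'   integrity (111/14/29 rows, category ranges, mask consistency).
#' @export
load_fixtures <- function(path = NULL) {
  path <- path %||% system.file("extdata", package = "stagemir")
  t2 <- readr::read_tsv(file.path(path, "table2_known_mirna_tpm.tsv"),
                        show_col_types = FALSE)
  t3 <- readr::read_tsv(file.path(path, "table3_novel_mirna.tsv"),
                        show_col_types = FALSE)
  t5 <- readr::read_tsv(file.path(path, "table5_degradome_targets.tsv"),
                        show_col_types = FALSE)
  if (nrow(t2) != 111) stop("stage-expression fixture must have 111 rows",
                            call. = FALSE)
  if (anyDuplicated(t2$mirna)) stop("duplicate miRNA names in fixture",
                                    call. = FALSE)
  if (nrow(t3) != 14) stop("novel-miRNA fixture must have 14 matures",
                           call. = FALSE)
  if (nrow(t5) != 29) stop("degradome fixture must have 29 targets",
                           call. = FALSE)
  if (any(!t5$cat_pbs %in% 0:4)) stop("degradome categories must be 0-4",
                                      call. = FALSE)
  ncat <- rowSums(!is.na(t5[c("cat_pbs", "cat_scr", "cat_antimir")]))
  if (any(ncat < 1)) stop("each degradome target needs >= 1 condition",
                          call. = FALSE)
  list(table2 = t2, table3 = t3, table5 = t5)
}

#' Repertoire summaries of a stage-expression table
#'
#' Detection is presence of a TPM value (the explicit mask); "absent but
#' expressed elsewhere" additionally requires the maximum TPM over detected
#' stages to exceed `tpm_threshold`, the published qualifier.
#'
#' @param table2 Stage-expression tibble (`mirna` + stage TPM columns).
#' @param stages Stage column names.
#' @param tpm_threshold Expression qualifier (default 10).
#' @return List of summary counts: `n_total`, `per_stage` (named vector),
#'   `n_all_stages`, `n_absent_somewhere`, `n_absent_both_larvae_expressed`,
#'   `n_absent_only_lf_expressed`, `most_abundant` (named by stage).
#' @export
repertoire_summary <- function(table2, stages = STAGES, tpm_threshold = 10) {
  m <- as.matrix(table2[stages])
  det <- !is.na(m)
  maxelse <- apply(ifelse(det, m, NA), 1, max, na.rm = TRUE)
  absent_lm_lf <- !det[, "LM"] & !det[, "LF"]
  only_lf <- !det[, "LF"] & rowSums(det) == length(stages) - 1
  list(
    n_total = nrow(table2),
    per_stage = colSums(det),
    n_all_stages = sum(rowSums(det) == length(stages)),
    n_absent_somewhere = sum(rowSums(det) < length(stages)),
    n_absent_both_larvae_expressed =
      sum(absent_lm_lf & maxelse > tpm_threshold),
    n_absent_only_lf_expressed = sum(only_lf & maxelse > tpm_threshold),
    most_abundant = apply(m, 2, function(x) {
      table2$mirna[which.max(ifelse(is.na(x), -Inf, x))]
    })
  )
}

#' Degradome summaries of the target table
#'
#' The representative category of a target is its PBS-library category
#' (the uninjected baseline).
#'
#' @param table5 Degradome target tibble.
#' @return List: `n_total`, `per_mirna` (named vector), `category_tally`
#'   (named vector over the PBS categories 0-4).
#' @export
degradome_summary <- function(table5) {
  tal <- table(factor(table5$cat_pbs, levels = 0:4))
  list(
    n_total = nrow(table5),
    per_mirna = sort(table(table5$mirna), decreasing = TRUE),
    category_tally = setNames(as.integer(tal), names(tal))
  )
}

#' All fixture-derived summary reports
#'
#' Computes the repertoire and degradome summaries with the same operations
#' used on synthetic or real data (no special-cased counting).
#'
#' @param fixtures Output of [load_fixtures()].
#' @return List with `repertoire` and `degradome` summaries.
#' @export
fixture_reports <- function(fixtures = load_fixtures()) {
  list(repertoire = repertoire_summary(fixtures$table2),
       degradome = degradome_summary(fixtures$table5))
}
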