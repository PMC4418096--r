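#' Configuration for the synthetic small-RNA study
#'
#' Defines a seeded synthetic genome, six stage libraries and degradome tag
#' sets with known ground truth, emulating the structure of a developmental
#' small-RNA experiment: bimodal read lengths (20-23 nt miRNA peak, 32-35 nt
#' piRNA-like peak), planted known/novel miRNA loci with stage-specific
#' abundances, and degradome profiles with controlled category structure.
#'
#' @param seed Integer master seed; all outputs are byte-identical given the
#'   config.
#' @param n_contigs,contig_length Genome shape.
#' @param n_known_mirnas Number of planted known miRNA genes.
#' @param n_novel_loci Number of planted novel hairpin loci.
#' @param stem_length,loop_length Novel hairpin geometry (nt).
#' @param read_depth Reads per stage library.
#' @param pirna_fraction Fraction of depth reserved for the 32-35 nt
#'   piRNA-like background.
#' @param adapter 3' adapter appended to simulated reads.
#' @param n_de,de_fold Planted differential miRNAs between adult male and
#'   female (fold change `de_fold` up in AF).
#' @param base_tpm_range Log-uniform range of per-miRNA baseline TPM.
#' @param novel_tpm Baseline TPM of planted novel matures.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 7L, n_contigs = 2L,
                              contig_length = 10000L, n_known_mirnas = 30L,
                              n_novel_loci = 5L, stem_length = 30L,
                              loop_length = 8L, read_depth = 1e6,
                              pirna_fraction = 0.3,
                              adapter = "TGGAATTCTCGGGTGCCAAGG",
                              n_de = 5L, de_fold = 8,
                              base_tpm_range = c(20, 1500),
                              novel_tpm = 100) {
  cfg <- list(seed = as.integer(seed), n_contigs = n_contigs,
              contig_length = contig_length,
              n_known_mirnas = n_known_mirnas, n_novel_loci = n_novel_loci,
              stem_length = stem_length, loop_length = loop_length,
              read_depth = read_depth, pirna_fraction = pirna_fraction,
              adapter = canonical_seq(adapter), n_de = n_de,
              de_fold = de_fold, base_tpm_range = base_tpm_range,
              novel_tpm = novel_tpm)
  class(cfg) <- "sim_config"
  cfg
}

rand_seq <- function(n, p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate a genome with planted miRNA loci
#'
#' Contigs of random background with embedded known-miRNA genes and novel
#' hairpin loci (GC-rich perfect stems designed to clear the MFE call
#' threshold). An infeasible hairpin request (stem too short to reach the
#' threshold even with the strongest stacks) raises a configuration error
#' carrying the computed bound.
#'
#' @param config A [simulation_config()].
#' @param mfe_threshold The discovery threshold the planted stems must be
#'   able to clear (default -20).
#' @param par Energy parameters (for the feasibility bound).
#' @return List: `genome` (catalog tibble), `known` (mature catalog),
#'   `novel_loci` (BED-like tibble of planted mature loci with truth
#'   sequences and arms), `config`.
#' @export
simulate_genome <- function(config, mfe_threshold = -20,
                            par = rna_energy_params()) {
  bound <- (config$stem_length - 1) * min(par$stack) +
    min(par$hairpin[is.finite(par$hairpin)])
  if (bound >= mfe_threshold) {
    stop(sprintf(paste0("hairpin spec infeasible: best attainable MFE with ",
                        "a %d bp stem is %.1f kcal/mol (threshold %.1f)"),
                 config$stem_length, bound, mfe_threshold), call. = FALSE)
  }
  set.seed(config$seed)
  contigs <- vapply(seq_len(config$n_contigs), function(i) {
    rand_seq(config$contig_length)
  }, character(1))
  names(contigs) <- paste0("contig", seq_len(config$n_contigs))

  ## known mature miRNA genes (22 nt)
  known_seq <- replicate(config$n_known_mirnas, rand_seq(22))
  known <- sequence_catalog(
    setNames(known_seq, sprintf("sim-miR-%02d", seq_len(config$n_known_mirnas))),
    class = "known_mirna"
  )

  ## novel hairpins: GC-rich left arm + loop + perfect reverse complement
  gc_p <- c(A = 0.15, C = 0.35, G = 0.35, T = 0.15)
  units <- character(config$n_novel_loci)
  mature5 <- character(config$n_novel_loci)
  for (i in seq_len(config$n_novel_loci)) {
    arm <- rand_seq(config$stem_length, gc_p)
    loop <- rand_seq(config$loop_length)
    units[i] <- paste0(arm, loop, revcomp(arm))
    mature5[i] <- substr(arm, 1, 22)
  }

  ## place inserts non-overlapping, round-robin across contigs
  inserts <- c(known_seq, units)
  labels <- c(rep("known", length(known_seq)), rep("novel", length(units)))
  ## plus strand throughout: a perfect hairpin is (near) its own reverse
  ## complement, so minus-strand planting adds nothing the plus strand does
  ## not already contain; strand handling is exercised at the unit level
  strand <- rep("+", length(inserts))
  slot_gap <- (config$contig_length - 200L) %/%
    ceiling(length(inserts) / config$n_contigs)
  placed <- list()
  slot <- rep(0L, config$n_contigs)
  for (k in seq_along(inserts)) {
    ci <- ((k - 1) %% config$n_contigs) + 1
    at <- 100L + slot[ci] * slot_gap        # 0-based insert offset
    ins <- inserts[k]
    substr(contigs[ci], at + 1L, at + nchar(ins)) <- ins
    placed[[k]] <- tibble::tibble(
      contig = names(contigs)[ci], insert_start = at,
      insert_end = at + nchar(ins), strand = strand[k], label = labels[k],
      idx = k
    )
    slot[ci] <- slot[ci] + 1L
  }
  placed <- dplyr::bind_rows(placed)

  ## mature read loci for the novel hairpins (mature = first 22 nt of the
  ## 5' arm of the planted unit, on the unit's strand)
  novel_rows <- placed[placed$label == "novel", ]
  ui <- match(novel_rows$idx, seq_along(inserts)) - length(known_seq)
  novel_loci <- tibble::tibble(
    name = sprintf("sim-novel-%d", seq_len(config$n_novel_loci)),
    contig = novel_rows$contig,
    start = novel_rows$insert_start,
    end = novel_rows$insert_start + 22L,
    strand = novel_rows$strand,
    mature = mature5[ui],
    precursor_unit = units[ui],
    arm = "5p"
  )
  list(genome = sequence_catalog(contigs, class = "genome"), known = known,
       novel_loci = novel_loci, config = config)
}

#' Expected TPM matrix of the simulated study
#'
#' Known miRNAs draw a log-uniform baseline shared across the six stages;
#' the first `n_de` of them are planted `de_fold`-fold up in AF relative to
#' AM (the planted differential set); novel matures sit at `novel_tpm`
#' everywhere.
#'
#' @param sim Output of [simulate_genome()].
#' @return Tibble `feature_name`, one TPM column per stage, `is_de`.
#' @export
expected_tpm <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  base <- exp(runif(cfg$n_known_mirnas, log(cfg$base_tpm_range[1]),
                    log(cfg$base_tpm_range[2])))
  tb <- tibble::tibble(feature_name = sim$known$name)
  for (s in STAGES) tb[[s]] <- base
  de <- seq_len(min(cfg$n_de, cfg$n_known_mirnas))
  tb$AF[de] <- tb$AF[de] * cfg$de_fold
  tb$is_de <- seq_len(nrow(tb)) %in% de
  nv <- tibble::tibble(feature_name = sim$novel_loci$name)
  for (s in STAGES) nv[[s]] <- cfg$novel_tpm
  nv$is_de <- FALSE
  out <- dplyr::bind_rows(tb, nv)
  ## rescale so the deepest stage's miRNA mass is 1 - pirna_fraction of the
  ## library, giving the bimodal length profile its miRNA peak; ratios (and
  ## hence fold changes) are preserved
  scale <- (1 - cfg$pirna_fraction) * 1e6 / max(colSums(out[STAGES]))
  for (s in STAGES) out[[s]] <- out[[s]] * scale
  out
}

#' Simulate the six stage libraries
#'
#' Per stage, each planted miRNA/novel mature receives a Poisson count with
#' mean `TPM * depth / 1e6`; the remaining depth is filled with random
#' 32-35 nt piRNA-like background; the 3' adapter is appended to every
#' read. Sequencing errors are off. With `dir` set, FASTQ files are written
#' (one per stage) and paths returned.
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Optional output directory for FASTQ files.
#' @param collapse Return collapsed (`seq`, `count`) tibbles instead of one
#'   row per read; with error-free reads this is an exact equivalence and
#'   keeps deep libraries cheap to hold in memory.
#' @return List with `libraries` (named list of read tibbles or file
#'   paths), `true_counts` (long tibble of planted counts), `expected`
#'   (the TPM matrix used).
#' @export
simulate_stage_libraries <- function(sim, dir = NULL, collapse = FALSE) {
  cfg <- sim$config
  exp_tpm <- expected_tpm(sim)
  matures <- c(sim$known$seq[match(exp_tpm$feature_name, sim$known$name)])
  ni <- match(exp_tpm$feature_name, sim$novel_loci$name)
  matures[!is.na(ni)] <- sim$novel_loci$mature[ni[!is.na(ni)]]
  libs <- list()
  truth <- list()
  for (si in seq_along(STAGES)) {
    st <- STAGES[si]
    set.seed(cfg$seed + 100L + si)
    lam <- exp_tpm[[st]] * cfg$read_depth / 1e6
    counts <- rpois(length(lam), lam)
    ## pirna_fraction 0 disables the background entirely; otherwise it
    ## fills the depth left over by the planted counts
    n_bg <- if (cfg$pirna_fraction == 0) 0L else {
      max(0L, cfg$read_depth - sum(counts))
    }
    if (n_bg > 0) {
      pool <- rand_seq(200000L)
      bg_len <- sample(32:35, n_bg, replace = TRUE,
                       prob = c(0.2, 0.4, 0.25, 0.15))
      bg_start <- sample.int(200000L - 35L, n_bg, replace = TRUE)
      bg <- substring(pool, bg_start, bg_start + bg_len - 1L)
    } else {
      bg <- character(0)
    }
    ## honour pirna_fraction approximately by construction: background
    ## fills depth - planted counts; planted TPMs are capped upstream
    seqs <- c(rep(matures, counts), bg)
    seqs <- paste0(seqs, cfg$adapter)
    seqs <- sample(seqs)
    if (collapse) {
      libs[[st]] <- collapse_reads(tibble::tibble(seq = seqs)) |>
        dplyr::mutate(stage = st)
    } else if (!is.null(dir)) {
      path <- file.path(dir, paste0(st, ".fastq"))
      con <- file(path, open = "wt")
      chunk <- 200000L
      for (off in seq(1L, length(seqs), by = chunk)) {
        sl <- seqs[off:min(off + chunk - 1L, length(seqs))]
        writeLines(c(rbind(paste0("@", st, "_", off:(off + length(sl) - 1L)),
                           sl, "+", strrep("I", nchar(sl)))), con)
      }
      close(con)
      libs[[st]] <- path
    } else {
      libs[[st]] <- tibble::tibble(read_id = paste0(st, "_",
                                                    seq_along(seqs)),
                                   seq = seqs, stage = st)
    }
    truth[[st]] <- tibble::tibble(feature_name = exp_tpm$feature_name,
                                  stage = st, count = counts)
  }
  list(libraries = libs, true_counts = dplyr::bind_rows(truth),
       expected = exp_tpm)
}

#' Simulate degradome tag sets with controlled categories
#'
#' Builds random transcripts, embeds a perfect complementary site for each
#' requested (miRNA, category) pair so that the canonical cleavage position
#' (opposite miRNA position 10) is realized, and emits 21 nt tags whose 5'
#' ends produce an abundance profile of exactly the requested category.
#' Conditions `PBS` and `SCR` carry the full signal; `ANTIMIR` suppresses
#' the planted tags of the antagomir-targeted miRNA.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param plan Tibble with `mirna` (name), `category` (0-4), and optionally
#'   `background_sites` (default 3).
#' @param seed Seed for transcript generation.
#' @param transcript_length Length of each synthetic transcript.
#' @param antagomir Name of the miRNA suppressed in the ANTIMIR condition
#'   (default: the first planned miRNA).
#' @return List: `transcripts` (catalog tibble), `tags` (named list of tag
#'   tibbles per condition), `truth` (planted calls with intended
#'   categories).
#' @export
simulate_degradome <- function(mirnas, plan, seed = 7L,
                               transcript_length = 1500L,
                               antagomir = NULL) {
  if (is.null(plan[["background_sites"]])) plan$background_sites <- 3L
  bad <- plan$category == 1 & plan$background_sites < 1
  if (any(bad)) {
    stop("category 1 requires at least one shared-maximum background site",
         call. = FALSE)
  }
  antagomir <- antagomir %||% plan$mirna[1]
  set.seed(seed)
  transcripts <- character(nrow(plan))
  truth <- list()
  tags_pbs <- list()
  tags_anti <- list()
  for (k in seq_len(nrow(plan))) {
    tx <- rand_seq(transcript_length)
    mi <- mirnas[[plan$mirna[k]]]
    L <- nchar(mi)
    cleave <- 600L + 7L * k            # keep sites away from the ends
    s <- cleave - L + 10L              # site window start
    substr(tx, s, s + L - 1L) <- revcomp(mi)
    transcripts[k] <- tx
    cat_k <- plan$category[k]
    nbg <- plan$background_sites[k]
    ## abundance design per category (site first, then background sites)
    ab <- switch(as.character(cat_k),
      "0" = c(5, rep(1, max(nbg, 1))),
      "1" = c(3, 3, rep(1, max(nbg - 1, 0))),
      "2" = c(2, 5, rep(1, max(nbg - 1, 2))),
      "3" = c(2, 5, rep(4, max(nbg - 1, 1))),
      "4" = c(1, rep(1, nbg))
    )
    bg_pos <- 100L + 30L * seq_len(length(ab) - 1L)
    pos <- c(cleave, bg_pos)
    for (j in seq_along(pos)) {
      tag <- substr(tx, pos[j], pos[j] + 20L)
      tags_pbs[[length(tags_pbs) + 1]] <- tibble::tibble(seq = tag,
                                                         count = ab[j])
      if (!(j == 1 && plan$mirna[k] == antagomir)) {
        tags_anti[[length(tags_anti) + 1]] <- tibble::tibble(seq = tag,
                                                             count = ab[j])
      }
    }
    truth[[k]] <- tibble::tibble(mirna = plan$mirna[k],
                                 transcript_id = paste0("tx", k),
                                 cleavage_position = cleave,
                                 category = cat_k,
                                 suppressed = plan$mirna[k] == antagomir)
  }
  tx_cat <- sequence_catalog(setNames(transcripts,
                                      paste0("tx", seq_len(nrow(plan)))),
                             class = "cds")
  pbs <- dplyr::bind_rows(tags_pbs) |>
    dplyr::summarise(count = sum(.data$count), .by = "seq")
  anti <- dplyr::bind_rows(tags_anti) |>
    dplyr::summarise(count = sum(.data$count), .by = "seq")
  list(transcripts = tx_cat,
       tags = list(PBS = pbs, SCR = pbs, ANTIMIR = anti),
       truth = dplyr::bind_rows(truth))
}
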