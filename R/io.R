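#' Read a paralog-pair codon alignment from FASTA
#'
#' Sequence IDs follow the `"taxon|locus"` convention (locus 0 or 1 for
#' the two paralogs of a post-duplication taxon; a bare taxon name for
#' the outgroup or other single-copy sequences). Codon columns containing
#' a gap in any sequence are removed at load; post-duplication taxa
#' represented by only one paralog are dropped with a warning (the model
#' does not handle paralog deletion); an in-frame stop codon is an error
#' naming the sequence and column.
#'
#' @param path FASTA file.
#' @param code A `genetic_code` (codon length 3 assumed for DNA input).
#' @return A `pair_alignment`.
#' @export
read_pair_alignment <- function(path, code = standard_code()) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), names(ss))
  seqs <- toupper(gsub("\\s", "", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  cl <- code$codon_length
  if (lens[1] %% cl != 0L) {
    stop(sprintf("alignment length %d is not a multiple of %d", lens[1], cl),
         call. = FALSE)
  }
  ncol <- unname(lens[1] %/% cl)
  chars <- do.call(rbind, strsplit(seqs, ""))
  col_of <- rep(seq_len(ncol), each = cl)
  gap <- apply(chars == "-", 2, any)
  gapped_cols <- unique(col_of[gap])
  if (length(gapped_cols)) {
    keep <- !(col_of %in% gapped_cols)
    chars <- chars[, keep, drop = FALSE]
    message(sprintf("removed %d codon column(s) with at least one gap",
                    length(gapped_cols)))
  }
  seqs <- apply(chars, 1, paste0, collapse = "")
  names(seqs) <- names(ss)
  # drop post-duplication taxa lacking the second paralog
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  taxon <- vapply(parts, `[[`, character(1), 1)
  locus <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else
                  NA_character_, character(1))
  for (tx in unique(taxon[!is.na(locus)])) {
    loci <- locus[taxon == tx & !is.na(locus)]
    if (!all(c("0", "1") %in% loci)) {
      warning(sprintf(
        "dropping taxon '%s': only one paralog present", tx))
      seqs <- seqs[taxon != tx]
      drop <- taxon != tx
      locus <- locus[drop]; taxon <- taxon[drop]
    }
  }
  if (!length(seqs)) stop("no usable sequences after filtering", call. = FALSE)
  pair_alignment(seqs, code)
}

#' Write a paralog-pair alignment to FASTA
#'
#' @param alignment A `pair_alignment`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pair_alignment <- function(alignment, path) {
  code <- alignment$code
  lines <- character(0)
  for (s in rownames(alignment$states)) {
    st <- alignment$states[s, ]
    cods <- ifelse(is.na(st), strrep("N", code$codon_length),
                   code$codons[st])
    lines <- c(lines, paste0(">", s), paste0(cods, collapse = ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a duplication tree to Newick
#'
#' @param tree A `duplication_tree`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_duplication_tree <- function(tree, path) {
  ape::write.tree(tree$phy, file = path)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize fit results to TSV
#'
#' One record per fitted model: the glance row joined with the tidy
#' parameter estimates (wide) and branch lengths.
#'
#' @param fits An `igc_fit` or list of them.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_fits_tsv <- function(fits, path) {
  if (inherits(fits, "igc_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    g <- glance(f)
    td <- tidy(f, branch_lengths = TRUE)
    wide <- tidyr::pivot_wider(td, names_from = "term",
                               values_from = "estimate")
    dplyr::bind_cols(g, wide)
  })
  write_tsv_file(dplyr::bind_rows(rows), path)
}

#' Run the simulator and archive its outputs
#'
#' Writes the simulated FASTA alignment, the Newick tree, the TSV event
#' log and a plain-text run manifest (seed, parameters, paths) into
#' `out_dir`.
#'
#' @inheritParams simulate_igc
#' @param out_dir Output directory (created if needed).
#' @return The `igc_sim`, invisibly.
#' @export
run_simulate <- function(params, tree, n_codons, code = standard_code(),
                         seed = 1, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_igc(params, tree, n_codons, code, seed = seed)
  write_pair_alignment(sim$alignment, file.path(out_dir, "alignment.fasta"))
  write_duplication_tree(tree, file.path(out_dir, "tree.nwk"))
  write_tsv_file(sim$events, file.path(out_dir, "events.tsv"))
  p <- params
  manifest <- c(
    sprintf("command\tsimulate"),
    sprintf("seed\t%d", seed),
    sprintf("n_codons\t%d", n_codons),
    sprintf("mode\t%s", p$mode),
    sprintf("kappa\t%g", p$kappa),
    if (p$mode == "omega") sprintf("omega\t%g", p$omega)
    else c(sprintf("omega_h\t%g", p$omega_h),
           sprintf("omega_n\t%g", p$omega_n)),
    sprintf("tau\t%g", p$tau),
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("igcodon")))
  )
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(sim)
}

#' Fit one or more models and write the results
#'
#' @inheritParams fit_igc
#' @param models Character vector of model tags.
#' @param out_dir Output directory.
#' @param ... Passed to [fit_igc()].
#' @return Named list of `igc_fit`, invisibly.
#' @export
run_fit <- function(alignment, tree, models = MODEL_TAGS,
                    code = alignment$code, out_dir = ".", ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- lapply(stats::setNames(models, models), function(m) {
    fit_igc(alignment, tree, m, code = code, ...)
  })
  write_fits_tsv(fits, file.path(out_dir, "fits.tsv"))
  invisible(fits)
}

#' Run the five-comparison model lattice and write statistics
#'
#' @inheritParams model_lattice
#' @param out_dir Output directory.
#' @return The lattice list, invisibly.
#' @export
run_lrt <- function(alignment, tree, code = alignment$code, out_dir = ".",
                    ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lat <- model_lattice(alignment, tree, code = code, ...)
  write_fits_tsv(lat$fits, file.path(out_dir, "fits.tsv"))
  write_tsv_file(lat$tests, file.path(out_dir, "lrt.tsv"))
  invisible(lat)
}

#' Compute and write per-branch labeled counts
#'
#' @inheritParams expected_counts
#' @param out_dir Output directory.
#' @return The `igc_counts`, invisibly.
#' @export
run_proportion <- function(fit, alignment, out_dir = ".", ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- expected_counts(fit, alignment, ...)
  write_tsv_file(tidy(counts), file.path(out_dir, "counts.tsv"))
  summary <- tibble::tibble(
    model = attr(counts, "model"),
    conditional = attr(counts, "conditional"),
    total_expected = sum(counts$expected),
    proportion_igc = attr(counts, "proportion_igc")
  )
  write_tsv_file(summary, file.path(out_dir, "proportion.tsv"))
  invisible(counts)
}

#' Run the branch-length and paralog-swap screens
#'
#' @inheritParams paralog_swap_check
#' @param cap Branch-length cap for [branch_length_screen()].
#' @param out_dir Output directory.
#' @param ... Passed to [fit_igc()].
#' @return A list with `branch_screen` and `swap` results, invisibly.
#' @export
run_screen <- function(alignment, tree, swap_taxon, code = alignment$code,
                       cap = 1.5, out_dir = ".", ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- fit_igc(alignment, tree, "omega-IGC", code = code, ...)
  bs <- branch_length_screen(fit, cap = cap)
  sw <- paralog_swap_check(alignment, tree, swap_taxon, code = code, ...)
  write_tsv_file(bs, file.path(out_dir, "branch_screen.tsv"))
  write_tsv_file(tibble::as_tibble(sw), file.path(out_dir, "swap_screen.tsv"))
  invisible(list(branch_screen = bs, swap = sw, fit = fit))
}
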