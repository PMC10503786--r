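#' Genetic-code machinery for paralog-pair substitution models
#'
#' A `genetic_code` object fixes the sense-codon alphabet shared by every
#' other component of the package: the ordered list of sense codons (the
#' single-locus state space), the stop triplets excluded from the state
#' space, the translation table, and the purine/pyrimidine classification
#' used to distinguish transitions from transversions. Codon order is
#' lexicographic over the nucleotide alphabet, so state indices -- and
#' therefore every rate matrix -- are reproducible across runs.
#'
#' @name genetic_code
NULL

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

new_genetic_code <- function(name, alphabet, codon_length, codons, stops, aa) {
  structure(
    list(
      name = name,
      alphabet = alphabet,
      codon_length = codon_length,
      codons = codons,
      stops = stops,
      aa = aa,
      n = length(codons),
      moves = NULL
    ),
    class = "genetic_code"
  )
}

all_triplets <- function(alphabet, codon_length) {
  grids <- rev(replicate(codon_length, alphabet, simplify = FALSE))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse columns for
  # lexicographic order over position 1, 2, 3.
  sort(apply(g[, rev(seq_len(codon_length)), drop = FALSE], 1, paste0, collapse = ""))
}

validate_genetic_code <- function(code) {
  trip <- all_triplets(code$alphabet, code$codon_length)
  if (!setequal(c(code$codons, code$stops), trip) ||
      anyDuplicated(c(code$codons, code$stops)) > 0) {
    stop("codons and stops must partition the set of triplets over the alphabet",
         call. = FALSE)
  }
  if (!all(code$codons %in% names(code$aa))) {
    stop("aa_map must cover every sense codon", call. = FALSE)
  }
  if (any(code$stops %in% names(code$aa))) {
    stop("aa_map must not assign an amino acid to a stop triplet", call. = FALSE)
  }
  if (is.unsorted(code$codons)) {
    stop("sense codons must be in lexicographic order", call. = FALSE)
  }
  code
}

#' The standard nuclear genetic code
#'
#' Returns the standard genetic code with its 61 sense codons in fixed
#' lexicographic order and the three stop triplets (TAA, TAG, TGA)
#' excluded from the state space. The translation table is taken from
#' [Biostrings::GENETIC_CODE].
#'
#' @return A `genetic_code` object with 61 sense codons.
#' @export
#' @examples
#' code <- standard_code()
#' code$n                    # 61
#' code$aa[["AAA"]]          # "K"
standard_code <- function() {
  tab <- Biostrings::GENETIC_CODE
  codons <- sort(names(tab)[tab != "*"])
  stops <- sort(names(tab)[tab == "*"])
  aa <- tab[codons]
  code <- new_genetic_code("standard", c("A", "C", "G", "T"), 3L,
                           codons, stops, aa)
  code <- validate_genetic_code(code)
  code$moves <- point_moves(code)
  code
}

#' Construct a reduced genetic code for exhaustive oracle computations
#'
#' A toy code is usable everywhere a `genetic_code` is accepted, but with a
#' state space small enough that likelihoods, stationary distributions and
#' expected counts can be cross-checked by brute-force enumeration over the
#' full pair-state space.
#'
#' @param alphabet Character vector of nucleotide symbols, a subset of
#'   A, C, G, T (the subset determines which changes count as transitions:
#'   A<->G and C<->T).
#' @param codon_length Number of nucleotides per "codon".
#' @param aa_map Named character vector mapping every non-stop triplet to an
#'   amino-acid symbol.
#' @param stops Character vector of triplets excluded from the state space
#'   (may be empty).
#' @param name Name for the code.
#' @return A `genetic_code` object.
#' @export
#' @examples
#' # 4 "codons" over {A,C} x {A,C}, two amino acids: 16 pair states
#' toy <- toy_code(c("A", "C"), 2,
#'                 c(AA = "K", AC = "K", CA = "T", CC = "T"))
#' toy$n^2
toy_code <- function(alphabet, codon_length, aa_map, stops = character(),
                     name = "toy") {
  if (!all(alphabet %in% c("A", "C", "G", "T"))) {
    stop("alphabet must be a subset of A, C, G, T", call. = FALSE)
  }
  trip <- all_triplets(alphabet, codon_length)
  codons <- sort(setdiff(trip, stops))
  if (!setequal(names(aa_map), codons)) {
    stop("aa_map must cover exactly the non-stop triplets", call. = FALSE)
  }
  code <- new_genetic_code(name, alphabet, as.integer(codon_length),
                           codons, sort(stops), aa_map[codons])
  code <- validate_genetic_code(code)
  code$moves <- point_moves(code)
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code '%s': %d sense codons, %d stops, alphabet {%s}, length %d>\n",
              x$name, x$n, length(x$stops),
              paste(x$alphabet, collapse = ","), x$codon_length))
  invisible(x)
}

is_transition <- function(a, b) {
  (a %in% PURINES & b %in% PURINES) | (a %in% PYRIMIDINES & b %in% PYRIMIDINES)
}

#' Enumerate admissible single-nucleotide point moves of a code
#'
#' Internal table of all sense-to-sense codon changes that differ at
#' exactly one nucleotide position: the raw material of the point-mutation
#' rate matrices.
#'
#' @param code A `genetic_code`.
#' @return A data frame with columns `from`, `to` (codon indices), `pos`,
#'   `to_nt` (the nucleotide introduced), `transition` (logical),
#'   `synonymous` (logical) and `aa_to`.
#' @keywords internal
point_moves <- function(code) {
  n <- code$n
  len <- code$codon_length
  mat <- do.call(rbind, strsplit(code$codons, ""))
  from <- integer(0); to <- integer(0); pos <- integer(0); to_nt <- character(0)
  codon_index <- stats::setNames(seq_len(n), code$codons)
  out <- vector("list", n * len * (length(code$alphabet) - 1L))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in seq_len(len)) {
      for (b in setdiff(code$alphabet, mat[i, p])) {
        cand <- mat[i, ]
        cand[p] <- b
        cand <- paste0(cand, collapse = "")
        j <- codon_index[cand]
        if (!is.na(j)) {
          k <- k + 1L
          out[[k]] <- list(from = i, to = unname(j), pos = p, to_nt = b)
        }
      }
    }
  }
  out <- out[seq_len(k)]
  df <- data.frame(
    from = vapply(out, `[[`, integer(1), "from"),
    to = vapply(out, `[[`, integer(1), "to"),
    pos = vapply(out, `[[`, integer(1), "pos"),
    to_nt = vapply(out, `[[`, character(1), "to_nt"),
    stringsAsFactors = FALSE
  )
  from_nt <- mat[cbind(df$from, df$pos)]
  df$transition <- is_transition(from_nt, df$to_nt)
  df$aa_from <- unname(code$aa[df$from])
  df$aa_to <- unname(code$aa[df$to])
  df$synonymous <- df$aa_from == df$aa_to
  df
}

# ---- pair-state indexing ----------------------------------------------------

#' Index arithmetic for ordered pair states
#'
#' The joint process tracks the ordered pair of sense codons occupying
#' corresponding positions of the two paralogs. Pair `(i, i')` maps to the
#' 1-based index `(i - 1) * n + i'`, a bijection with `1..n^2`.
#'
#' @param first,second 1-based sense-codon indices.
#' @param n Number of sense codons in the code.
#' @return `pair_index()` returns the 1-based pair index;
#'   `pair_unindex()` returns a two-column matrix of (first, second) indices.
#' @export
pair_index <- function(first, second, n) {
  (first - 1L) * n + second
}

#' @rdname pair_index
#' @param idx 1-based pair index.
#' @export
pair_unindex <- function(idx, n) {
  cbind(first = ((idx - 1L) %/% n) + 1L, second = ((idx - 1L) %% n) + 1L)
}

n_diff_positions <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Classify a single pair-state change by origin and effect
#'
#' Given a change in which exactly one member of the ordered codon pair is
#' replaced, lists the admissible mutational origins and their
#' classification. A point-mutation origin is admissible iff the changed
#' triplets differ at exactly one nucleotide; an IGC origin is admissible
#' iff the changed triplet becomes identical to the (unchanged) partner
#' triplet -- IGC copies the partner's codon wholesale, so it can change
#' several nucleotides at once. Synonymy is judged on the changed locus;
#' homogenization compares the new amino acid of the changed locus with the
#' partner's amino acid (every nonsynonymous IGC change is homogenizing by
#' construction).
#'
#' @param from,to Length-2 character vectors of codons `c(first, second)`,
#'   or 1-based pair indices.
#' @param code A `genetic_code`.
#' @return A tibble with one row per admissible origin and columns
#'   `origin` ("point" or "igc"), `synonymy`, `homogenization`
#'   ("homogenizing", "nonhomogenizing" or NA for synonymous changes) and
#'   `ts_tv` ("transition", "transversion" or "multi-site"). Zero rows mean
#'   the transition has rate zero under the model.
#' @export
#' @examples
#' code <- standard_code()
#' classify_change(c("TTT", "TTA"), c("TTA", "TTA"), code)  # point AND igc
classify_change <- function(from, to, code) {
  from <- as_codon_pair(from, code)
  to <- as_codon_pair(to, code)
  changed <- which(from != to)
  if (length(changed) == 0L) {
    stop("from and to are identical", call. = FALSE)
  }
  if (length(changed) == 2L) {
    stop("both loci changed: such transitions have rate 0", call. = FALSE)
  }
  locus <- changed
  partner <- 3L - locus
  old <- from[locus]; new <- to[locus]; part <- from[partner]
  aa_new <- code$aa[[new]]
  aa_old <- code$aa[[old]]
  aa_part <- code$aa[[part]]
  syn <- aa_new == aa_old
  hom <- if (syn) NA_character_ else {
    if (aa_new == aa_part) "homogenizing" else "nonhomogenizing"
  }
  ndiff <- n_diff_positions(old, new)
  rows <- list()
  if (ndiff == 1L) {
    p <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])
    ts <- is_transition(substr(old, p, p), substr(new, p, p))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      origin = "point", synonymy = if (syn) "synonymous" else "nonsynonymous",
      homogenization = hom,
      ts_tv = if (ts) "transition" else "transversion"
    )
  }
  if (new == part) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      origin = "igc", synonymy = if (syn) "synonymous" else "nonsynonymous",
      homogenization = if (syn) NA_character_ else "homogenizing",
      ts_tv = if (ndiff == 1L) {
        p <- which(strsplit(old, "")[[1]] != strsplit(new, "")[[1]])
        if (is_transition(substr(old, p, p), substr(new, p, p))) {
          "transition"
        } else "transversion"
      } else "multi-site"
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(origin = character(), synonymy = character(),
                          homogenization = character(), ts_tv = character()))
  }
  dplyr::bind_rows(rows)
}

as_codon_pair <- function(x, code) {
  if (is.numeric(x) && length(x) == 1L) {
    ij <- pair_unindex(as.integer(x), code$n)
    x <- c(code$codons[ij[1, "first"]], code$codons[ij[1, "second"]])
  }
  if (!is.character(x) || length(x) != 2L || !all(x %in% code$codons)) {
    stop("pair state must be two sense codons or a valid pair index",
         call. = FALSE)
  }
  x
}
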