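#' Species trees with an annotated duplication node
#'
#' A `duplication_tree` is a rooted species tree on which a single-copy
#' gene lineage becomes a two-paralog lineage at an explicitly designated
#' duplication node. Every branch tipward of the duplication node carries
#' the pair regime (the n^2-state joint process); every other branch,
#' including the outgroup branch, carries the single-copy regime. Branches
#' subsequent to the first post-duplication speciation are flagged
#' countable: they are the only branches over which IGC proportions are
#' estimated, because immediately after the duplication the paralogs are
#' identical and IGC leaves no trace. Branch lengths are in expected
#' point-mutation substitutions per codon.
#'
#' @param phy An [ape::phylo] tree (unary nodes allowed, so the
#'   duplication point can sit on a stem branch), or a Newick string/file
#'   via [read_duplication_tree()].
#' @param duplication_node Label of the duplication node (must exist in
#'   `phy$node.label`); never inferred from tree shape.
#' @param countable Optional character vector of child-node labels whose
#'   parent branches are countable; by default every branch strictly below
#'   the first post-duplication speciation node is countable.
#' @return A `duplication_tree` object.
#' @export
duplication_tree <- function(phy, duplication_node, countable = NULL) {
  stopifnot(inherits(phy, "phylo"))
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labels <- c(phy$tip.label,
              if (is.null(phy$node.label)) rep(NA_character_, nnode)
              else phy$node.label)
  dup <- which(labels == duplication_node)
  if (length(dup) != 1L || dup <= ntip) {
    stop("duplication_node must name exactly one internal node", call. = FALSE)
  }
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  edges <- tibble::tibble(
    parent = phy$edge[, 1], child = phy$edge[, 2],
    length = phy$edge.length,
    child_label = labels[phy$edge[, 2]]
  )
  if (any(edges$length < 0)) stop("branch lengths must be >= 0", call. = FALSE)
  root <- setdiff(edges$parent, edges$child)
  kids <- split(edges$child, edges$parent)
  descend <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      ch <- kids[[as.character(v)]]
      out <- c(out, ch); stack <- c(stack, ch)
    }
    out
  }
  below_dup <- descend(dup)
  edges$regime <- ifelse(edges$child %in% below_dup, "pair", "single_copy")
  # first post-duplication speciation: walk down from the duplication node
  # through any unary chain until a node with >= 2 children
  fs <- dup
  repeat {
    ch <- kids[[as.character(fs)]]
    if (is.null(ch) || length(ch) >= 2L) break
    fs <- ch
  }
  if (fs <= ntip) {
    stop("no speciation event below the duplication node", call. = FALSE)
  }
  if (is.null(countable)) {
    below_fs <- descend(fs)
    edges$countable <- edges$child %in% below_fs
  } else {
    edges$countable <- edges$child_label %in% countable
    if (any(edges$countable & edges$regime != "pair")) {
      stop("countable branches must carry the pair regime", call. = FALSE)
    }
  }
  # postorder over nodes (children before parents)
  post <- integer(0)
  visit <- function(v) {
    for (ch in kids[[as.character(v)]]) visit(ch)
    post <<- c(post, v)
  }
  visit(root)
  tips <- tibble::tibble(
    id = seq_len(ntip), label = phy$tip.label,
    regime = ifelse(seq_len(ntip) %in% below_dup, "pair", "single_copy")
  )
  structure(
    list(phy = phy, labels = labels, edges = edges, root = root,
         dup = dup, first_spec = fs, postorder = post, tips = tips,
         n_tip = ntip),
    class = "duplication_tree"
  )
}

#' Read a duplication-annotated species tree from Newick
#'
#' @param source A Newick string or path to a Newick file. Unary node
#'   labels are preserved, so a duplication point on a stem branch can be
#'   written as `( (clade)dup:0.1, outgroup:0.5);`.
#' @inheritParams duplication_tree
#' @return A `duplication_tree`.
#' @export
read_duplication_tree <- function(source, duplication_node, countable = NULL) {
  phy <- if (file.exists(source)) ape::read.tree(source)
         else ape::read.tree(text = source)
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  duplication_tree(phy, duplication_node, countable = countable)
}

#' @export
print.duplication_tree <- function(x, ...) {
  cat(sprintf(
    "<duplication_tree: %d tips (%d paired), duplication at '%s', %d countable branches>\n",
    x$n_tip, sum(x$tips$regime == "pair"), x$labels[x$dup],
    sum(x$edges$countable)))
  invisible(x)
}

#' Replace the branch lengths of a duplication tree
#'
#' @param tree A `duplication_tree`.
#' @param lengths Numeric vector in the tree's edge-table order.
#' @return The tree with updated lengths.
#' @export
set_branch_lengths <- function(tree, lengths) {
  stopifnot(length(lengths) == nrow(tree$edges), all(lengths >= 0))
  tree$edges$length <- as.numeric(lengths)
  tree$phy$edge.length <- as.numeric(lengths)
  tree
}

#' Tabulate the branches of a duplication tree
#'
#' @param x A `duplication_tree`.
#' @param ... Unused.
#' @return A tibble with parent, child, child label, length, regime and
#'   countable flag per branch.
#' @exportS3Method generics::tidy
tidy.duplication_tree <- function(x, ...) {
  x$edges
}

# ---- alignments -------------------------------------------------------------

#' In-memory paralog-pair codon alignment
#'
#' Holds gap-free codon columns keyed by taxon. The outgroup (and any
#' single-copy taxon) contributes one codon sequence; every
#' post-duplication taxon contributes an ordered pair of paralog
#' sequences, named `"taxon|0"` and `"taxon|1"`.
#'
#' @param sequences Named character vector (or list) of DNA sequences, all
#'   the same length and a multiple of the code's codon length. Names
#'   follow the `"taxon|locus"` convention with locus 0 or 1; a bare taxon
#'   name marks a single-copy sequence.
#' @param code A `genetic_code`.
#' @return A `pair_alignment`: integer codon-state matrix (`states`, one
#'   row per sequence slot), taxon table and the code.
#' @export
pair_alignment <- function(sequences, code) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  if (lens[1] %% code$codon_length != 0L) {
    stop(sprintf("sequence length %d is not a multiple of the codon length %d",
                 lens[1], code$codon_length), call. = FALSE)
  }
  ncol <- unname(lens[1] %/% code$codon_length)
  codon_index <- stats::setNames(seq_len(code$n), code$codons)
  states <- matrix(NA_integer_, length(sequences), ncol,
                   dimnames = list(names(sequences), NULL))
  for (s in seq_along(sequences)) {
    cods <- substring(sequences[[s]],
                      seq(1, lens[1], by = code$codon_length),
                      seq(code$codon_length, lens[1], by = code$codon_length))
    bad <- which(cods %in% code$stops)
    if (length(bad)) {
      stop(sprintf("in-frame stop codon in sequence '%s' at codon column %d",
                   names(sequences)[s], bad[1]), call. = FALSE)
    }
    idx <- codon_index[cods]
    unknown <- is.na(idx) & !grepl("[-N?]", cods)
    if (any(unknown)) {
      stop(sprintf("invalid codon '%s' in sequence '%s' at column %d",
                   cods[which(unknown)[1]], names(sequences)[s],
                   which(unknown)[1]), call. = FALSE)
    }
    states[s, ] <- unname(idx)  # NA = gap/ambiguity (treated as missing)
  }
  parts <- strsplit(rownames(states), "|", fixed = TRUE)
  taxon <- vapply(parts, `[[`, character(1), 1)
  locus <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                  character(1))
  if (any(!is.na(locus) & !locus %in% c("0", "1"))) {
    stop("sequence IDs must be 'taxon' or 'taxon|0' / 'taxon|1'",
         call. = FALSE)
  }
  tab <- tibble::tibble(slot = rownames(states), taxon = taxon, locus = locus)
  paired <- tapply(tab$locus, tab$taxon, function(l) all(c("0", "1") %in% l))
  taxa <- tibble::tibble(taxon = names(paired), paired = as.logical(paired))
  structure(
    list(states = states, slots = tab, taxa = taxa, code = code,
         n_col = ncol),
    class = "pair_alignment"
  )
}

#' @export
print.pair_alignment <- function(x, ...) {
  cat(sprintf("<pair_alignment: %d taxa (%d paired), %d codon columns>\n",
              nrow(x$taxa), sum(x$taxa$paired), x$n_col))
  invisible(x)
}

#' Empirical nucleotide frequencies of an alignment
#'
#' Pooled over all sites of all sequences (paralogs and outgroup), the
#' default F1x4 frequency policy.
#'
#' @param alignment A `pair_alignment`.
#' @return Named frequency vector over the code's alphabet.
#' @export
empirical_pi <- function(alignment) {
  code <- alignment$code
  st <- alignment$states[!is.na(alignment$states)]
  chars <- unlist(strsplit(code$codons[st], ""))
  counts <- table(factor(chars, levels = code$alphabet))
  stats::setNames(as.numeric(counts) / sum(counts), code$alphabet)
}

# ---- transition operators ---------------------------------------------------

# expm(Q t) %*% V, dense Pade for small state spaces, uniformization
# (Poisson-weighted powers of I + Q/lambda) for large sparse ones.
expm_apply <- function(Q, t, V, dense_cutoff = 700) {
  V <- as.matrix(V)
  if (t == 0) return(V)
  if (is.matrix(Q)) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
    return(P %*% V)
  }
  if (nrow(Q) <= dense_cutoff) {
    P <- as.matrix(Matrix::expm(Q * t))
    return(P %*% V)
  }
  lambda <- max(-Matrix::diag(Q))
  if (lambda == 0) return(V)
  lt <- lambda * t
  m <- stats::qpois(1e-13, lt, lower.tail = FALSE) + 2L
  Pm <- Q / lambda + Matrix::Diagonal(nrow(Q))
  w <- stats::dpois(0:m, lt)
  acc <- V * w[1]
  term <- V
  for (k in seq_len(m)) {
    term <- as.matrix(Pm %*% term)
    acc <- acc + w[k + 1] * term
  }
  acc / sum(w)
}

#' Map a pair-state partial vector through the duplication event
#'
#' The duplication deterministically copies the single-copy state i into
#' the pair (i, i), so the single-copy partial likelihood at the
#' duplication node reads off the diagonal pair entries.
#'
#' @param partial Numeric vector of length n^2, or an n^2 x k matrix of
#'   per-pattern partials.
#' @param n Number of sense codons.
#' @return Vector of length n (or n x k matrix).
#' @export
map_duplication <- function(partial, n) {
  idx <- pair_index(seq_len(n), seq_len(n), n)
  if (is.matrix(partial)) {
    if (nrow(partial) != n * n) stop("partial has wrong length", call. = FALSE)
    partial[idx, , drop = FALSE]
  } else {
    if (length(partial) != n * n) stop("partial has wrong length", call. = FALSE)
    partial[idx]
  }
}

# ---- pruning ----------------------------------------------------------------

# Compress alignment columns into unique patterns over the tree's tips.
# Returns per-tip observed state vectors (pair indices for paired tips),
# pattern weights, and the column -> pattern map.
compress_patterns <- function(alignment, tree) {
  code <- alignment$code
  n <- code$n
  obs <- list()
  for (k in seq_len(tree$n_tip)) {
    lab <- tree$tips$label[k]
    if (tree$tips$regime[k] == "pair") {
      s0 <- paste0(lab, "|0"); s1 <- paste0(lab, "|1")
      if (!all(c(s0, s1) %in% rownames(alignment$states))) {
        stop(sprintf("tree tip '%s' needs paralog sequences '%s' and '%s'",
                     lab, s0, s1), call. = FALSE)
      }
      a <- alignment$states[s0, ]; b <- alignment$states[s1, ]
      st <- ifelse(is.na(a) | is.na(b), NA_integer_, pair_index(a, b, n))
    } else {
      if (!lab %in% rownames(alignment$states)) {
        stop(sprintf("tree tip '%s' missing from alignment", lab),
             call. = FALSE)
      }
      st <- alignment$states[lab, ]
    }
    obs[[lab]] <- st
  }
  key <- do.call(paste, c(obs, sep = "_"))
  u <- !duplicated(key)
  pat_of_col <- match(key, key[u])
  list(obs = lapply(obs, function(v) v[u]),
       weights = tabulate(pat_of_col, nbins = sum(u)),
       pat_of_col = pat_of_col, n_pat = sum(u))
}

col_max <- function(m) {
  tm <- t(m)
  tm[cbind(seq_len(nrow(tm)), max.col(tm, ties.method = "first"))]
}

tip_partial <- function(states, size, n_pat) {
  M <- matrix(0, size, n_pat)
  miss <- is.na(states)
  if (any(miss)) M[, miss] <- 1
  ok <- which(!miss)
  M[cbind(states[ok], ok)] <- 1
  M
}

# Core pruning over patterns. Returns per-pattern log-likelihoods and,
# optionally, the inside partials and scaling logs per node (for the
# expected-counts machinery).
prune_patterns <- function(alignment, tree, params, code,
                           prm = NULL, srm = NULL, keep_partials = FALSE,
                           cp = NULL) {
  n <- code$n
  if (is.null(prm)) prm <- pair_rate_matrix(params, code)
  if (is.null(srm)) {
    srm <- single_rate_matrix(single_interval_params(params), code)
  }
  if (is.null(cp)) cp <- compress_patterns(alignment, tree)
  npat <- cp$n_pat
  edges <- tree$edges
  edge_of_child <- stats::setNames(seq_len(nrow(edges)), edges$child)
  partials <- vector("list", length(tree$labels))
  logscale <- matrix(0, 1, npat)
  stored <- if (keep_partials) list(partials = vector("list", length(tree$labels)),
                                    scales = vector("list", length(tree$labels)))
            else NULL
  node_space <- function(v) {
    # the space in which the partial AT node v (from below) lives
    if (v == tree$dup) return("single")  # after the duplication mapping
    ch_e <- which(edges$parent == v)
    if (length(ch_e)) {
      if (edges$regime[ch_e[1]] == "pair") "pair" else "single"
    } else {
      if (tree$tips$regime[v] == "pair") "pair" else "single"
    }
  }
  node_scale <- vector("list", length(tree$labels))
  for (v in tree$postorder) {
    if (v <= tree$n_tip) {
      lab <- tree$tips$label[v]
      size <- if (tree$tips$regime[v] == "pair") n * n else n
      partials[[v]] <- tip_partial(cp$obs[[lab]], size, npat)
      node_scale[[v]] <- rep(0, npat)
    } else {
      ch_e <- which(edges$parent == v)
      pr <- NULL
      sc <- rep(0, npat)
      for (e in ch_e) {
        c_node <- edges$child[e]
        Q <- if (edges$regime[e] == "pair") prm$q else srm$q
        contrib <- expm_apply(Q, edges$length[e], partials[[c_node]])
        pr <- if (is.null(pr)) contrib else pr * contrib
        sc <- sc + node_scale[[c_node]]
      }
      if (v == tree$dup) {
        pr <- map_duplication(pr, n)
      }
      mx <- col_max(pr)
      mx[mx == 0] <- 1
      pr <- sweep(pr, 2, mx, "/")
      sc <- sc + log(mx)
      partials[[v]] <- pr
      node_scale[[v]] <- sc
    }
    if (keep_partials) {
      stored$partials[[v]] <- partials[[v]]
      stored$scales[[v]] <- node_scale[[v]]
    }
  }
  f <- srm$stationary
  root_pr <- partials[[tree$root]]
  if (nrow(root_pr) != n) {
    stop("root partial is not in single-copy space; check the duplication node",
         call. = FALSE)
  }
  lik <- as.numeric(crossprod(f, root_pr))
  site_ll <- log(lik) + node_scale[[tree$root]]
  list(site_ll = as.numeric(site_ll), patterns = cp, prm = prm, srm = srm,
       stored = stored)
}

#' Log-(composite-)likelihood of a paralog-pair alignment
#'
#' Felsenstein pruning with two regimes: pair-state partial vectors below
#' the duplication node, mapped to single-copy partials at the duplication
#' (the duplication copies state i to the pair (i, i)), and single-copy
#' pruning above it with omegaN as the nonsynonymous factor under the
#' omegaH/omegaN mode, each interval normalized to one expected
#' point-mutation substitution per codon per time unit. The root sits at
#' the outgroup divergence with the single-copy stationary distribution.
#' Sites are treated as independent, so for low recombination the value is
#' a composite likelihood. Identical columns share one computation.
#'
#' @param alignment A `pair_alignment`.
#' @param tree A `duplication_tree` whose tips match the alignment's taxa.
#' @param params An `igc_params` object.
#' @param code A `genetic_code`; defaults to the alignment's code.
#' @param per_site Return the vector of per-column log-likelihoods instead
#'   of their sum.
#' @return The total log-likelihood (or per-column vector).
#' @export
log_likelihood <- function(alignment, tree, params, code = alignment$code,
                           per_site = FALSE) {
  if (alignment$n_col == 0L) stop("empty alignment", call. = FALSE)
  pr <- prune_patterns(alignment, tree, params, code)
  if (per_site) {
    pr$site_ll[pr$patterns$pat_of_col]
  } else {
    sum(pr$site_ll * pr$patterns$weights)
  }
}

#' Log-likelihood of a single codon column
#'
#' @param column Named vector/list of observed codon states for one
#'   column: a codon string for single-copy taxa, a length-2 character
#'   vector of codons for paired taxa (named by taxon).
#' @inheritParams log_likelihood
#' @return The column's log-likelihood.
#' @export
site_log_likelihood <- function(column, tree, params, code) {
  seqs <- character(0)
  for (tx in names(column)) {
    v <- column[[tx]]
    if (length(v) == 2L) {
      seqs[paste0(tx, "|0")] <- v[1]
      seqs[paste0(tx, "|1")] <- v[2]
    } else {
      seqs[tx] <- v
    }
  }
  aln <- pair_alignment(seqs, code)
  log_likelihood(aln, tree, params, code)
}
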