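# Library curation: RNA-side redundancy clustering, template/target date
# split, and the all-to-all similarity-vs-binding-mode analysis.

#' Remove RNA redundancy by single-linkage sequence clustering
#'
#' Clusters the RNA chains of the complexes by global sequence identity
#' and mutual coverage (one internal pass; the cluster relation is the
#' transitive closure of pairwise identity >= `identity_cutoff` AND
#' min(coverage) >= `coverage_cutoff`). Only the RNA side is clustered -
#' protein redundancy is deliberately untouched. The cluster
#' representative is the member with the best (numerically smallest)
#' resolution; ties go to the earliest deposit date, then lexicographic
#' id.
#'
#' @param complexes list of [binary_complex] objects.
#' @param identity_cutoff,coverage_cutoff clustering thresholds
#'   (default 0.99 each).
#' @return Object of class `complex_library`: `complexes` (the
#'   representatives), `clusters` (named list representative id ->
#'   member ids), `all_complexes`, and an empty `split`.
#' @export
cluster_redundancy <- function(complexes, identity_cutoff = 0.99,
                               coverage_cutoff = 0.99) {
  n <- length(complexes)
  ids <- vapply(complexes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate complex ids")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  seqs <- vapply(complexes, function(b) b$rna$sequence, "")
  lens <- nchar(seqs)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    # cheap guard: identical-coverage demands near-equal lengths
    if (min(lens[i], lens[j]) / max(lens[i], lens[j]) < coverage_cutoff) next
    al <- align_global(seqs[i], seqs[j], "rna")
    # mutual coverage: matched (gap-free) columns relative to each chain
    cov <- min(nrow(al$aligned_pairs) / lens[i], nrow(al$aligned_pairs) / lens[j])
    if (al$identity >= identity_cutoff && cov >= coverage_cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  clusters <- split(seq_len(n), roots)
  res <- vapply(complexes, function(b) ifelse(is.na(b$resolution), Inf, b$resolution), 1)
  dates <- as.Date(vapply(complexes, function(b) format(b$deposit_date), ""))
  reps <- vapply(clusters, function(members) {
    o <- order(res[members], dates[members], ids[members])
    members[o[1]]
  }, 1L)
  keep <- sort(reps)
  structure(list(
    complexes = complexes[keep],
    clusters = setNames(lapply(clusters, function(m) ids[m]), ids[reps]),
    all_complexes = complexes,
    split = NULL
  ), class = "complex_library")
}

#' @export
print.complex_library <- function(x, ...) {
  cat(sprintf("<complex_library> %d representatives (%d complexes, %d clusters)%s\n",
              length(x$complexes), length(x$all_complexes %||% x$complexes),
              length(x$clusters),
              if (!is.null(x$split)) sprintf(", split %d/%d templates/targets",
                                             sum(x$split == "template"),
                                             sum(x$split == "target")) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a library into templates and targets by deposit date
#'
#' Sorts the representatives by ascending deposit date (ties broken by
#' id) and designates the older `ceiling(template_fraction * n)` as
#' templates, the rest as targets.
#'
#' @param library a `complex_library` (or plain list of complexes).
#' @param template_fraction fraction of the library used as templates
#'   (default 0.8).
#' @return The library with `split` filled in: a named factor
#'   (`template` / `target`) indexed by complex id.
#' @export
split_by_date <- function(library, template_fraction = 0.8) {
  if (!inherits(library, "complex_library"))
    library <- structure(list(complexes = library, clusters = NULL,
                              all_complexes = library, split = NULL),
                         class = "complex_library")
  cx <- library$complexes
  ids <- vapply(cx, `[[`, "", "id")
  dates <- as.Date(vapply(cx, function(b) format(b$deposit_date), ""))
  if (anyNA(dates))
    stop("missing deposit dates for: ", paste(ids[is.na(dates)], collapse = ", "))
  o <- order(dates, ids)
  n <- length(cx)
  n_templates <- ceiling(template_fraction * n)
  split <- rep("target", n)
  split[o[seq_len(n_templates)]] <- "template"
  library$split <- setNames(factor(split, levels = c("template", "target")), ids)
  library
}

#' Templates or targets of a split library
#' @param library a split `complex_library`.
#' @param role `"template"` or `"target"`.
#' @return List of [binary_complex] objects.
#' @export
library_subset <- function(library, role = c("template", "target")) {
  role <- match.arg(role)
  if (is.null(library$split)) stop("library has no template/target split")
  library$complexes[library$split == role]
}

pair_struct_scores <- function(a, b) {
  ap <- align_protein(a$protein, b$protein)
  ar <- align_rna(a$rna, b$rna)
  s <- complex_structural_score(min(1, ap$normalized_score),
                                min(1, ar$normalized_score))
  i <- irmsd(a, b, ap, ar)
  list(tm = s$tm_score, rna = s$rna_score_normalized,
       complex_score = s$complex_score, irmsd = i)
}

#' All-to-all pairwise comparison of a complex library
#'
#' For every unordered pair of complexes, records either the sequence
#' similarity (complex identity = min over monomers, complex coverage =
#' min over the four chains) or the structural scores (TM-score,
#' normalized RNA score, complex score), plus the IRMSD. Pairs are
#' canonicalized by id, so the result is independent of input order. In
#' `seq_local` mode, pairs with complex coverage < `coverage_min` are
#' flagged `excluded`.
#'
#' @param library a `complex_library` or list of complexes.
#' @param mode `"seq_local"`, `"seq_global"` or `"structural"`.
#' @param coverage_min exclusion threshold for local-alignment coverage
#'   (default 0.3).
#' @param progress print a line every 50 pairs.
#' @return data.frame, one row per unordered pair: ids, scores, `irmsd`
#'   (`NA` when incomparable, with `irmsd_defined` FALSE), and `excluded`.
#' @export
all_to_all <- function(library, mode = c("seq_local", "seq_global", "structural"),
                       coverage_min = 0.3, progress = FALSE) {
  mode <- match.arg(mode)
  cx <- if (inherits(library, "complex_library")) library$complexes else library
  ids <- vapply(cx, `[[`, "", "id")
  o <- order(ids)
  cx <- cx[o]; ids <- ids[o]
  n <- length(cx)
  rows <- list()
  # structural alignments cached for irmsd in sequence modes too
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- cx[[i]]; b <- cx[[j]]
    ap <- align_protein(a$protein, b$protein)
    ar <- align_rna(a$rna, b$rna)
    ir <- irmsd(a, b, ap, ar)
    row <- data.frame(id_a = ids[i], id_b = ids[j],
                      irmsd = as.numeric(ir),
                      irmsd_defined = !is.na(ir), excluded = FALSE)
    if (mode == "structural") {
      s <- complex_structural_score(min(1, ap$normalized_score),
                                    min(1, ar$normalized_score))
      row$tm_score <- s$tm_score
      row$rna_score <- s$rna_score_normalized
      row$complex_score <- s$complex_score
    } else {
      ss <- complex_sequence_similarity(a, b,
                                        if (mode == "seq_local") "local" else "global")
      row$complex_identity <- ss$complex_identity
      row$complex_coverage <- ss$complex_coverage
      if (mode == "seq_local") row$excluded <- ss$complex_coverage < coverage_min
    }
    rows[[length(rows) + 1L]] <- row
    if (progress && length(rows) %% 50 == 0)
      message("all_to_all: ", length(rows), " pairs done")
  }
  do.call(rbind, rows)
}

#' Fraction of similar binding modes in similarity bins
#'
#' Bins the pair table by a similarity column (bin width 0.05 over [0,1],
#' half-open `[x, x+w)` with the last bin closed) and reports, per bin,
#' the fraction of pairs with IRMSD <= `irmsd_threshold`. Empty bins
#' carry `NA`, not 0. Pairs flagged `excluded` or with undefined IRMSD
#' are dropped first.
#'
#' @param pair_table output of [all_to_all()].
#' @param similarity_column column name to bin on.
#' @param irmsd_threshold binding-mode similarity threshold (default 5).
#' @param bin_width default 0.05.
#' @return data.frame of class `transition_curve`: `bin_lo`, `bin_hi`,
#'   `count`, `fraction_similar`.
#' @export
transition_curve <- function(pair_table, similarity_column,
                             irmsd_threshold = 5.0, bin_width = 0.05) {
  stopifnot(similarity_column %in% names(pair_table), nrow(pair_table) > 0)
  t <- pair_table[!pair_table$excluded & pair_table$irmsd_defined, ]
  edges <- seq(0, 1, by = bin_width)
  x <- pmin(pmax(t[[similarity_column]], 0), 1)
  bin <- pmin(findInterval(x, edges), length(edges) - 1L)  # last bin closed
  cnt <- tabulate(bin, nbins = length(edges) - 1L)
  sim <- tabulate(bin[t$irmsd <= irmsd_threshold], nbins = length(edges) - 1L)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    count = cnt,
                    fraction_similar = ifelse(cnt > 0, sim / cnt, NA_real_))
  class(out) <- c("transition_curve", "data.frame")
  out
}

#' Structure-vs-sequence quadrant fractions
#'
#' Joins a structural and a sequence pair table on the pair key and
#' reports the fraction of pairs in the four quadrants cut by
#' `x = x_cut` (structural score) and `y = y_cut` (sequence identity);
#' the cut lines belong to the upper/right quadrants (closed lower
#' edges). Also reports the split of the `x >= x_cut` pairs by sequence
#' identity.
#'
#' @param pair_table_struct structural-mode [all_to_all()] table.
#' @param pair_table_seq sequence-mode table over the same pairs.
#' @param x_cut structural transition point (default 0.45).
#' @param y_cut sequence transition point (default 0.25).
#' @return List with `fractions` (named: `lower_left`, `lower_right`,
#'   `upper_left`, `upper_right`, summing to 1), `n`, and
#'   `given_struct_ge_cut` (fractions of high/low sequence identity among
#'   pairs with structural score >= `x_cut`).
#' @export
quadrant_stats <- function(pair_table_struct, pair_table_seq,
                           x_cut = 0.45, y_cut = 0.25) {
  key <- function(t) paste(t$id_a, t$id_b)
  ks <- key(pair_table_struct); kq <- key(pair_table_seq)
  if (!setequal(ks, kq) || length(ks) != length(kq))
    stop("pair tables are not keyed by the same pairs")
  m <- match(ks, kq)
  x <- pair_table_struct$complex_score
  y <- pair_table_seq$complex_identity[m]
  n <- length(x)
  fr <- c(lower_left = mean(x < x_cut & y < y_cut),
          lower_right = mean(x >= x_cut & y < y_cut),
          upper_left = mean(x < x_cut & y >= y_cut),
          upper_right = mean(x >= x_cut & y >= y_cut))
  hi <- x >= x_cut
  cond <- if (any(hi)) c(high_seq = mean(y[hi] >= y_cut),
                         low_seq = mean(y[hi] < y_cut))
          else c(high_seq = NA_real_, low_seq = NA_real_)
  list(fractions = fr, n = n, given_struct_ge_cut = cond)
}
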