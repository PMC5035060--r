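# Redundancy clustering, date split, all-to-all tables, transition
# curves and quadrant statistics.

# lightweight stand-in complexes: clustering and splitting only touch
# id / rna sequence / resolution / deposit date
stub_complex <- function(id, rna_seq, resolution = 2.0, date = "2005-01-01") {
  structure(list(id = id, rna = list(sequence = rna_seq),
                 resolution = resolution, deposit_date = as.Date(date)),
            class = "binary_complex")
}

rand_rna_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
}

test_that("identical RNAs cluster; representative has best resolution", {
  s <- rand_rna_seq(30, 1)
  cx <- list(stub_complex("a_AB", s, 2.9, "2001-01-01"),
             stub_complex("b_AB", s, 2.0, "2003-01-01"),
             stub_complex("c_AB", s, 2.5, "2002-01-01"),
             stub_complex("d_AB", rand_rna_seq(30, 2), 1.8))
  lib <- cluster_redundancy(cx)
  expect_length(lib$complexes, 2)
  expect_setequal(names(lib$clusters), c("b_AB", "d_AB"))
  expect_setequal(lib$clusters[["b_AB"]], c("a_AB", "b_AB", "c_AB"))
})

test_that("identity 0.98 does not cluster at the 0.99 cutoff", {
  s <- rand_rna_seq(50, 3)
  s2 <- s
  substr(s2, 25, 25) <- setdiff(c("A", "C", "G", "U"),
                                substr(s, 25, 25))[1]  # 49/50 identity
  expect_equal(align_global(s, s2, "rna")$identity, 0.98)
  lib <- cluster_redundancy(list(stub_complex("a_AB", s),
                                 stub_complex("b_AB", s2, 1.9)))
  expect_length(lib$complexes, 2)
})

test_that("clustering equals the transitive-closure oracle and is invariant", {
  # planted duplicate groups plus distinct complexes
  seqs <- c(replicate(3, rand_rna_seq(28, 10)), # triplet 1
            replicate(2, rand_rna_seq(24, 11)), # pair 2
            vapply(12:16, function(s) rand_rna_seq(26, s), ""))
  cx <- lapply(seq_along(seqs), function(i)
    stub_complex(sprintf("s%02d_AB", i), seqs[i], 2 + 0.05 * i))
  lib <- cluster_redundancy(cx)
  # oracle: union-find over the pairwise >= 0.99 identity+coverage relation
  n <- length(cx)
  rel <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n) if (i < j) {
    al <- align_global(seqs[i], seqs[j], "rna")
    cov <- nrow(al$aligned_pairs) / max(nchar(seqs[i]), nchar(seqs[j]))
    rel[i, j] <- al$identity >= 0.99 && cov >= 0.99
  }
  comp <- oracle_components(rel)
  expect_equal(length(lib$clusters), length(unique(comp)))
  canon <- function(clusters)
    sort(vapply(clusters, function(m) paste(sort(m), collapse = ","), ""))
  want <- split(vapply(cx, `[[`, "", "id"), comp)
  expect_equal(unname(canon(lib$clusters)), unname(canon(want)))

  # permutation invariance
  lib2 <- cluster_redundancy(cx[c(5, 2, 9, 1, 10, 3, 7, 4, 8, 6)])
  expect_equal(unname(canon(lib2$clusters)), unname(canon(lib$clusters)))
  # idempotence: clustering the representatives yields singletons
  lib3 <- cluster_redundancy(lib$complexes)
  expect_true(all(lengths(lib3$clusters) == 1))
})

test_that("split_by_date: 80/20 by ascending date, deterministic ties", {
  cx <- lapply(1:10, function(i)
    stub_complex(sprintf("x%02d_AB", i), rand_rna_seq(20, 100 + i),
                 date = sprintf("%d-06-01", 2000 + i)))
  lib <- split_by_date(cx)
  split <- lib$split
  expect_equal(sum(split == "template"), 8)
  ids <- names(split)
  expect_true(all(split[ids[1:8]] == "template"))   # 2001..2008
  expect_true(all(split[ids[9:10]] == "target"))    # 2009..2010

  # 439 complexes under the ceiling convention: 352 / 87
  big <- lapply(1:439, function(i)
    stub_complex(sprintf("y%03d_AB", i), "ACGU",
                 date = format(as.Date("1995-01-01") + i * 13)))
  s2 <- split_by_date(big)$split
  expect_equal(as.integer(table(s2)), c(ceiling(0.8 * 439), 439L - ceiling(0.8 * 439)))

  # all-same-date: deterministic id tie-break, stable under input order
  same <- lapply(1:5, function(i)
    stub_complex(sprintf("z%d_AB", i), "ACGU", date = "2005-01-01"))
  a <- split_by_date(same)$split
  b <- split_by_date(rev(same))$split
  expect_identical(a[sort(names(a))], b[sort(names(b))])

  bad <- list(stub_complex("m1_AB", "ACGU", date = NA))
  expect_error(split_by_date(bad), "m1_AB")
})

make_mode_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # two same-mode near-copies and one alternative-mode copy
      p1 <- make_complex_pair(fixture_spec(seed = 301, noise_sigma = 0.2))
      p2 <- make_complex_pair(fixture_spec(seed = 301, binding_mode_b = 2))
      a <- p1$a; a$id <- "cplx1_AB"
      b <- p1$b; b$id <- "cplx2_AB"
      d <- p2$b; d$id <- "cplx3_AB"
      cache <<- list(a, b, d)
    }
    cache
  }
})

test_that("all_to_all: row count, canonical order, planted regimes", {
  cx <- make_mode_library()
  tab <- all_to_all(cx, "structural")
  expect_equal(nrow(tab), 3)   # C(3,2)
  key <- paste(tab$id_a, tab$id_b)
  # same-mode near-copy pair: high score, low IRMSD
  r12 <- tab[key == "cplx1_AB cplx2_AB", ]
  expect_gt(r12$complex_score, 0.9)
  expect_lt(r12$irmsd, 5)
  # alternative-mode pair: high monomer similarity but dissimilar mode
  r13 <- tab[key == "cplx1_AB cplx3_AB", ]
  expect_gt(r13$complex_score, 0.9)
  expect_gt(r13$irmsd, 10)
  expect_equal(tab$complex_score, pmin(tab$tm_score, tab$rna_score))

  # input order does not matter (pairs are canonicalized)
  tab2 <- all_to_all(rev(cx), "structural")
  expect_equal(tab2, tab)

  # sequence modes share the pair key set and flag low local coverage
  tseq <- all_to_all(cx, "seq_local")
  expect_equal(paste(tseq$id_a, tseq$id_b), key)
  expect_equal(tseq$excluded, tseq$complex_coverage < 0.3)
})

test_that("identical complexes give score 1 and IRMSD 0", {
  pr <- make_complex_pair(fixture_spec(seed = 303))
  a <- pr$a; a$id <- "one_AB"
  b <- pr$a; b$id <- "two_AB"
  tab <- all_to_all(list(a, b), "structural")
  expect_equal(tab$complex_score, 1, tolerance = 1e-6)
  expect_equal(tab$irmsd, 0, tolerance = 1e-8)
})

fake_pairs <- function(score, irmsd) {
  data.frame(id_a = sprintf("a%03d", seq_along(score)),
             id_b = sprintf("b%03d", seq_along(score)),
             complex_score = score, irmsd = irmsd,
             irmsd_defined = TRUE, excluded = FALSE)
}

test_that("transition_curve bins, fractions, and empty-bin markers", {
  t1 <- fake_pairs(runif(200), rep(0, 200))
  c1 <- transition_curve(t1, "complex_score")
  expect_true(all(c1$fraction_similar[c1$count > 0] == 1))
  t2 <- fake_pairs(runif(200), rep(20, 200))
  c2 <- transition_curve(t2, "complex_score")
  expect_true(all(c2$fraction_similar[c2$count > 0] == 0))
  expect_true(all(is.na(c2$fraction_similar[c2$count == 0])))

  # two-regime step exactly at the 0.5 bin edge
  set.seed(81)
  sc <- runif(400)
  t3 <- fake_pairs(sc, ifelse(sc > 0.5, 1, 15))
  c3 <- transition_curve(t3, "complex_score")
  lo <- c3$bin_lo + 1e-9
  expect_true(all(c3$fraction_similar[c3$count > 0 & lo > 0.5] == 1))
  expect_true(all(c3$fraction_similar[c3$count > 0 & c3$bin_hi < 0.5 + 1e-9] == 0))

  # weighted-average consistency
  overall <- mean(t3$irmsd <= 5)
  expect_equal(sum(c3$fraction_similar * c3$count, na.rm = TRUE) / sum(c3$count),
               overall)

  # score exactly 1 lands in the last (closed) bin
  t4 <- fake_pairs(c(1, 1), c(0, 0))
  c4 <- transition_curve(t4, "complex_score")
  expect_equal(c4$count[nrow(c4)], 2L)
  expect_equal(sum(c4$count), 2L)
})

test_that("quadrant_stats fractions, conditional split, boundary closure", {
  str_tab <- fake_pairs(rep(0.9, 10), 0)
  seq_tab <- str_tab; names(seq_tab)[3] <- "complex_identity"
  q <- quadrant_stats(str_tab, seq_tab)
  expect_equal(unname(q$fractions["upper_right"]), 1)
  expect_equal(sum(q$fractions), 1)

  # uniform grid: fractions equal quadrant areas
  g <- expand.grid(x = seq(0.005, 0.995, 0.01), y = seq(0.005, 0.995, 0.01))
  st <- fake_pairs(g$x, 0); st$id_a <- sprintf("a%05d", seq_len(nrow(g)))
  st$id_b <- sprintf("b%05d", seq_len(nrow(g)))
  sq <- st; sq$complex_identity <- g$y; sq$complex_score <- NULL
  q2 <- quadrant_stats(st, sq, x_cut = 0.45, y_cut = 0.25)
  expect_equal(unname(q2$fractions["lower_left"]), 0.45 * 0.25, tolerance = 0.02)
  expect_equal(unname(q2$fractions["upper_right"]), 0.55 * 0.75, tolerance = 0.02)
  expect_equal(unname(q2$given_struct_ge_cut["high_seq"]), 0.75, tolerance = 0.02)

  # the cut point itself belongs to the upper-right quadrant
  bt <- fake_pairs(0.45, 0)
  bq <- bt; bq$complex_identity <- 0.25; bq$complex_score <- NULL
  q3 <- quadrant_stats(bt, bq)
  expect_equal(unname(q3$fractions["upper_right"]), 1)

  expect_error(quadrant_stats(str_tab, seq_tab[1:5, ]), "same pairs")
})
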