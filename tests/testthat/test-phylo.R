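test_that("pairwise distances follow the closed forms", {
  expect_equal(pairwise_distance("ACGT", "ACGA", model = "p"), 0.25)
  expect_equal(pairwise_distance("ACGT", "ACGT", model = "p"), 0)
  expect_equal(pairwise_distance("ACGT", "ACGT", model = "K2P"), 0)
  ## P = 0.1, Q = 0: 1 transition in 10 sites
  a <- "AAAAAAAAAA"
  b <- "GAAAAAAAAA"
  expect_equal(pairwise_distance(a, b, model = "K2P"), -0.5 * log(0.8),
               tolerance = 1e-12)
  ## gap/ambiguity columns drop out pairwise
  expect_equal(pairwise_distance("AC-GT", "ACNGA", model = "p"), 0.25)
  expect_error(pairwise_distance("----", "AAAA"), "no valid")
  ## saturation breaks the K2P log domain
  expect_error(pairwise_distance("AGAGAGAGAG", "GAGAGAGAGA", "K2P"),
               "saturation")
})

test_that("K2P distances agree with an independent reference implementation", {
  set.seed(12)
  for (i in 1:10) {
    a <- random_dna(300)
    b <- strsplit(a, "")[[1]]
    flip <- sample(300, 25)
    for (j in flip) b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1)
    b <- paste(b, collapse = "")
    bin <- ape::as.DNAbin(t(sapply(list(a = a, b = b), function(s)
      strsplit(tolower(s), "")[[1]])))
    ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                   pairwise.deletion = TRUE))["a", "b"]
    expect_equal(pairwise_distance(a, b, "K2P"), unname(ref),
                 tolerance = 1e-9)
  }
})

test_that("three-taxon neighbor joining matches the closed form", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ exactly recovers additive matrices, quartet oracle agrees", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    dm <- ape::cophenetic.phylo(gen)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    tr <- nj_tree(dm)
    ## recovered tree reproduces every leaf-to-leaf path length
    dd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(dd - dm)), 1e-8)
    ## and the topology matches the generating tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
  }
  ## independent least-squares quartet oracle on 4-taxon matrices
  for (i in 1:20) {
    gen <- ape::rtree(4, br = function(k) runif(k, 0.1, 1))
    dm <- ape::cophenetic.phylo(gen)
    dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
    tr <- nj_tree(dm)
    partner_oracle <- orc_best_quartet(dm)
    ## taxon 1's cherry partner in the NJ tree
    t1 <- rownames(dm)[1]
    pp <- ape::prop.part(tr)
    cherries <- Filter(function(p) length(p) == 2, lapply(pp, function(p)
      tr$tip.label[p]))
    comp <- Filter(function(p) length(p) == 2,
                   lapply(pp, function(p) setdiff(tr$tip.label, tr$tip.label[p])))
    pairs <- c(cherries, comp)
    with_t1 <- Filter(function(p) t1 %in% p, pairs)
    expect_true(length(with_t1) >= 1)
    expect_equal(setdiff(with_t1[[1]], t1), partner_oracle)
  }
})

test_that("ultrametric ties still reproduce the input path lengths", {
  dm <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(dm) <- 0
  tr <- nj_tree(dm)
  dd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_lt(max(abs(dd - dm)), 1e-8)
})

test_that("negative NJ branches are clamped with length transferred", {
  ## a non-additive matrix known to produce a negative NJ branch
  dm <- matrix(c(0.000, 2.655, 3.721, 9.082,
                 2.655, 0.000, 5.729, 2.017,
                 3.721, 5.729, 0.000, 8.984,
                 9.082, 2.017, 8.984, 0.000), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  raw0 <- ape::nj(stats::as.dist(dm))
  expect_true(any(raw0$edge.length < 0))  # fixture sanity
  raw <- ape::nj(as.dist(dm))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(sum(tr$edge.length), sum(raw$edge.length))
})

test_that("bootstrap supports saturate for clearly divergent groups", {
  set.seed(55)
  base <- strsplit(random_dna(300), "")[[1]]
  other <- base
  flip <- sample(300, 20)
  for (j in flip) other[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                             other[j]), 1)
  noise_copy <- function(ch, k = 2) {
    pos <- sample(300, k)
    for (j in pos) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(g1a = noise_copy(base), g1b = noise_copy(base),
            g1c = noise_copy(base),
            g2a = noise_copy(other), g2b = noise_copy(other),
            g2c = noise_copy(other))
  tr <- bootstrap_support(seqs, n_reps = 200, seed = 3)
  mono <- clade_check(tr, list(g1 = c("g1a", "g1b", "g1c"),
                               g2 = c("g2a", "g2b", "g2c")))
  expect_true(all(mono))
  ## the bipartition separating the two groups is in every replicate
  pp <- ape::prop.part(tr)
  grp_nodes <- which(vapply(pp, function(p) {
    tl <- sort(tr$tip.label[p])
    identical(tl, c("g1a", "g1b", "g1c")) ||
      identical(tl, c("g2a", "g2b", "g2c"))
  }, logical(1)))
  expect_true(length(grp_nodes) >= 1)
  expect_true(all(tr$node.label[grp_nodes] > 95))

  ## reproducibility and the single-replicate degenerate case
  tr2 <- bootstrap_support(seqs, n_reps = 200, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrap_support(seqs, n_reps = 1, seed = 4)
  expect_true(all(tr1$node.label %in% c(0L, 100L)))
})

test_that("monophyly follows bipartitions with singleton convention", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  res <- clade_check(tr, list(ab = c("A", "B"), ac = c("A", "C"),
                              solo = "A"))
  expect_equal(unname(res), c(TRUE, FALSE, TRUE))
  expect_error(clade_check(tr, list(bad = "Z")), "unknown taxon")
})

test_that("HRM calls and barcode clades agree on an end-to-end synthetic pair", {
  ## species pair: B carries 5 GC->AT substitutions (lower Tm), no indel
  set.seed(444)
  a <- strsplit(random_dna(162, gc = 0.6), "")[[1]]
  gc_pos <- which(a %in% c("G", "C"))[c(40, 45, 50, 55, 60)]
  b <- a
  b[gc_pos] <- sample(c("A", "T"), 5, replace = TRUE)
  amp_a <- paste(a, collapse = ""); amp_b <- paste(b, collapse = "")
  tm_a <- predict_tm_nn(amp_a)$tm_c
  tm_b <- predict_tm_nn(amp_b)$tm_c
  expect_gt(abs(tm_a - tm_b), 0.3)

  ## thermo-coupled simulation: group centers = predicted Tm + dye offset
  dye <- 1.1
  groups <- data.frame(label = c("PG", "PN"), n = c(6, 6),
                       tm_center_c = c(tm_a, tm_b) + dye,
                       tm_jitter_sd_c = 0.05)
  sim <- simulate_cohort(cohort_spec(groups, config = run_config(seed = 6)))
  refs <- list(PG = sim$truth$sample_id[1:3], PN = sim$truth$sample_id[7:9])
  res <- hrm_authenticate(sim$curves, refs, reference_label = "PG")
  truth <- setNames(sim$truth$true_label, sim$truth$sample_id)
  expect_equal(res$calls$call, unname(truth[res$calls$sample_id]))

  ## per-sample barcode sequences with private SNPs -> NJ clades
  noise_seq <- function(ch) {
    j <- sample(162, 1)
    ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(setNames(replicate(6, noise_seq(a)), sim$truth$sample_id[1:6]),
            setNames(replicate(6, noise_seq(b)), sim$truth$sample_id[7:12]))
  tr <- nj_tree(dist_matrix(seqs, model = "K2P"))
  mono <- clade_check(tr, split(sim$truth$sample_id, sim$truth$true_label))
  expect_true(all(mono))
  ## 100% concordance between melt-based calls and barcode clade membership
  cc <- concordance(res$calls, truth)
  expect_equal(cc$percent_agreement, 100)
})
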