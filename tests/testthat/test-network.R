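test_that("pair enumeration yields each unordered pair once, in order", {
  expect_equal(nrow(enumerate_pairs(c("D", "A", "C", "B"))), 6)
  p <- enumerate_pairs(c("B", "A"))
  expect_equal(p$gene_a, "A")
  expect_equal(p$gene_b, "B")
  expect_error(enumerate_pairs("A"), "at least 2")

  gem <- make_toy_gem(matrix(c(rep(1, 4), 1:4, 4:1), nrow = 3, byrow = TRUE))
  # filter drops the flat gene
  p2 <- enumerate_pairs(gem, gene_filter = function(x) stats::var(x) > 0)
  expect_equal(nrow(p2), 1)
  expect_error(enumerate_pairs(gem, gene_filter = function(x) FALSE), "at least 2")
})

test_that("gene prefiltering by variance and prevalence works and defaults to off", {
  set.seed(2)
  gem <- make_toy_gem(rbind(rep(0.01, 20), runif(20, 0, 10), c(rep(0, 15), runif(5, 5, 9))))
  expect_equal(nrow(filter_genes(gem)), 3)
  expect_equal(rownames(filter_genes(gem, min_variance = 0.1)), c("G02", "G03"))
  expect_equal(rownames(filter_genes(gem, min_fraction = 0.5, expression_floor = 1)),
               "G02")
})

test_that("evaluate_edge is symmetric and canonicalizes its record", {
  set.seed(9)
  sim <- generate_gem(planted_gem_spec(1, 1, 1, n_genes = 8,
                                       groups = c(a = 60, b = 60), seed = 4))
  gem <- sim$gem
  r1 <- evaluate_edge(gem, "G0001", "G0002", detector = fast_detector())
  r2 <- evaluate_edge(gem, "G0002", "G0001", detector = fast_detector())
  expect_identical(r1, r2)
  expect_true(r1$gene_a < r1$gene_b)
  expect_false(r1$skipped)
  expect_error(evaluate_edge(gem, "G0001", "NOPE"), "not present")
})

test_that("edges with too few pairwise-complete samples are skipped with a reason", {
  gem <- make_toy_gem(matrix(runif(40, 0, 10), nrow = 2))
  gem[2, 1:15] <- NA
  rec <- evaluate_edge(gem, "G01", "G02", min_samples = 10)
  expect_true(rec$skipped)
  expect_match(rec$skip_reason, "pairwise-complete")
  expect_true(is.na(rec$nmi))
  ok <- evaluate_edge(gem, "G01", "G02", min_samples = 5, detector = fast_detector())
  expect_false(ok$skipped)
  expect_equal(ok$n_samples_used, 5)
})

test_that("build_network keeps only records passing both criteria", {
  rec <- tibble::tibble(
    gene_a = c("A", "A", "B", "C"), gene_b = c("B", "C", "C", "D"),
    nmi = c(0.99, 0.99, 0.5, 0.98),
    blobs_log = 2L, blobs_dog = 2L, blobs_doh = 1L,
    n_methods_multimodal = c(2L, 1L, 2L, 2L),
    passed_blob = c(TRUE, FALSE, TRUE, TRUE),
    passed_mi = c(TRUE, TRUE, FALSE, TRUE),
    n_samples_used = 100L, skipped = FALSE, skip_reason = NA_character_
  )
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(tidy(net)), 2)
  expect_equal(nrow(tidy(net, all = TRUE)), 4)
  expect_equal(glance(net)$n_edges, 2)

  expect_error(build_network(rec[c(1, 1), ]), "duplicate")
  expect_error(build_network(dplyr::mutate(rec, gene_a = gene_b, gene_b = c("A", "A", "B", "C"))),
               "canonically")

  empty <- build_network(rec[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 0)
})

test_that("raising thresholds never adds edges (monotonicity)", {
  sim <- generate_gem(planted_gem_spec(2, 2, 2, n_genes = 14,
                                       groups = c(a = 80, b = 80), seed = 31))
  nets <- lapply(c(0.1, 0.3, 0.6, 0.97), function(tau) {
    craft_network(sim$gem, mi_threshold = tau, detector = fast_detector())
  })
  sizes <- vapply(nets, function(n) nrow(n$edges), integer(1))
  expect_true(all(diff(sizes) <= 0))

  k_sizes <- vapply(1:3, function(k) {
    nrow(craft_network(sim$gem, mi_threshold = 0.1,
                       detector = fast_detector(k_required = k))$edges)
  }, integer(1))
  expect_true(all(diff(k_sizes) <= 0))
})

test_that("the network is independent of evaluation order and worker count", {
  sim <- generate_gem(planted_gem_spec(1, 1, 1, n_genes = 8,
                                       groups = c(a = 50, b = 50), seed = 13))
  n1 <- craft_network(sim$gem, mi_threshold = 0.3, detector = fast_detector(),
                      threads = 1)
  n2 <- craft_network(sim$gem, mi_threshold = 0.3, detector = fast_detector(),
                      threads = 2)
  expect_identical(n1$records, n2$records)
  expect_true(compare_networks(n1, n2))

  # evaluating pairs in scrambled order rebuilds the identical network
  pairs <- enumerate_pairs(sim$gem)
  grid <- bin_grid_from_gem(sim$gem)
  set.seed(1)
  shuffled <- pairs[sample(nrow(pairs)), ]
  recs <- dplyr::bind_rows(lapply(seq_len(nrow(shuffled)), function(i) {
    evaluate_edge(sim$gem, shuffled$gene_a[i], shuffled$gene_b[i], grid = grid,
                  mi_threshold = 0.3, detector = fast_detector())
  }))
  n3 <- build_network(recs)
  expect_equal(n3$edges, n1$edges)
})

test_that("every reported edge satisfies both printed criteria", {
  sim <- generate_gem(planted_gem_spec(2, 2, 2, n_genes = 14,
                                       groups = c(a = 80, b = 80), seed = 77))
  net <- craft_network(sim$gem, mi_threshold = 0.25, detector = fast_detector())
  if (nrow(net$edges) > 0) {
    expect_true(all(net$edges$nmi >= 0.25))
    expect_true(all(net$edges$n_methods_multimodal >= 2))
    expect_true(all(net$edges$passed_blob & net$edges$passed_mi))
  }
  expect_false(anyDuplicated(paste(net$records$gene_a, net$records$gene_b)) > 0)
})

test_that("axis-flipped runs select identical edges; a broken comparison is caught", {
  sim <- generate_gem(planted_gem_spec(1, 1, 1, n_genes = 8,
                                       groups = c(a = 50, b = 50), seed = 19))
  expect_true(verify_orientation_invariance(sim$gem, mi_threshold = 0.3,
                                            detector = fast_detector()))

  # negative control: perturbing one record must be detected
  net <- craft_network(sim$gem, mi_threshold = 0.3, detector = fast_detector())
  broken <- net
  broken$records$nmi[1] <- broken$records$nmi[1] + 1e-3
  expect_false(compare_networks(net, broken))
  broken2 <- net
  broken2$records$blobs_log[2] <- broken2$records$blobs_log[2] + 1L
  expect_false(compare_networks(net, broken2))
})
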