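test_that("annotation files parse in both dialects", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tg1\tg2", "T2\tother\tg2\tg3\tg3"), f)
  ann <- read_annotations(f, "gmt")
  expect_equal(ann$terms$T1, c("g1", "g2"))
  expect_equal(ann$terms$T2, c("g2", "g3"))  # duplicate gene collapsed

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tT1", "g2\tT1", "g1\tT1"), f2)
  ann2 <- read_annotations(f2, "two_column")
  expect_equal(sort(ann2$terms$T1), c("g1", "g2"))

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), f3)
  expect_warning(ann3 <- read_annotations(f3, "two_column"), "empty")
  expect_length(ann3$terms, 0)

  writeLines("T1\tonly-desc", f)
  expect_error(read_annotations(f, "gmt"), "line 1")
})

test_that("fisher enrichment reproduces the exact hypergeometric tail", {
  # N = 20, module of 5, term of 5, overlap 4:
  # tail = [C(5,4)C(15,1) + C(5,5)C(15,0)] / C(20,5) = 76/15504
  nodes <- sprintf("g%02d", 1:20)
  p <- setNames(c(rep(1, 5), rep(2, 15)), nodes)
  ann <- annotation_set(list(T1 = nodes[c(1:4, 6)]))
  res <- fisher_enrichment(p, ann)
  r <- res[res$module == "1" & res$term == "T1", ]
  expect_equal(r$k, 4)
  expect_equal(r$p_raw, 76 / 15504, tolerance = 1e-12)

  # k = 0 gives the full tail, p = 1
  ann0 <- annotation_set(list(T0 = nodes[6:10]))
  res0 <- fisher_enrichment(p, ann0)
  expect_equal(res0$p_raw[res0$module == "1"], 1)

  # module == background forces k = t, p = 1
  p_all <- setNames(rep(1, 20), nodes)
  res_all <- fisher_enrichment(p_all, annotation_set(list(T1 = nodes[1:7])))
  expect_equal(res_all$p_raw, 1)

  expect_error(fisher_enrichment(p, ann, background = character()), "empty")
})

test_that("fisher tail matches brute-force enumeration and fisher.test on all small tables", {
  for (N in c(8, 15, 25)) {
    nodes <- sprintf("g%02d", seq_len(N))
    for (K in c(2, floor(N / 3), floor(N / 2))) {
      for (t_n in c(1, floor(N / 3))) {
        for (k in 0:min(K, t_n)) {
          if (t_n - k > N - K) next
          oracle <- fisher_tail_oracle(k, K, t_n, N)
          ours <- phyper(k - 1, t_n, N - t_n, K, lower.tail = FALSE)
          expect_equal(ours, oracle, tolerance = 1e-10)
          tab <- matrix(c(k, K - k, t_n - k, N - K - t_n + k), 2, byrow = TRUE)
          ft <- fisher.test(tab, alternative = "greater")$p.value
          expect_equal(ours, ft, tolerance = 1e-8)
        }
      }
    }
  }
})

test_that("bonferroni filter uses the family size with an inclusive boundary", {
  res <- data.frame(module = "1", term = sprintf("T%d", 1:4),
                    k = 1, K = 2, t = 2, N = 10,
                    p_raw = c(0.001 / 4, 0.001 / 4 + 1e-9, 0.5, 1e-8),
                    significant = NA)
  out <- bonferroni_filter(res, alpha = 0.001)
  expect_equal(attr(out, "threshold"), 0.001 / 4)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE))

  one <- bonferroni_filter(res[3, ], alpha = 0.001)
  expect_false(one$significant)  # 0.5 > 0.001
  single <- res[1, ]; single$p_raw <- 0.0005
  expect_true(bonferroni_filter(single, alpha = 0.001)$significant)

  expect_equal(nrow(bonferroni_filter(res[0, ], 0.001)), 0)
})

test_that("multi-module summaries tally per-term module counts", {
  res <- data.frame(
    module = c("1", "3", "1", "2", "1"),
    term = c("A", "A", "B", "C", "C"),
    p_raw = 1e-9, significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  s <- multi_module_summary(res)
  expect_equal(s$per_term[["A"]], 2)
  expect_equal(s$max_modules, 2)
  expect_equal(as.integer(s$histogram), c(2, 1))  # counts {1,1,2}

  empty <- multi_module_summary(data.frame(module = character(), term = character(),
                                           p_raw = numeric(), significant = logical()))
  expect_equal(empty$max_modules, 0)
})

test_that("cross-organism overlap groups terms by shared count", {
  ov <- cross_organism_overlap(list(c("A", "B"), c("B", "C")))
  expect_setequal(ov[["1"]], c("A", "C"))
  expect_equal(ov[["2"]], "B")

  six <- cross_organism_overlap(rep(list("X"), 6))
  expect_equal(six[["6"]], "X")

  disjoint <- cross_organism_overlap(list("A", "B", "C"))
  expect_setequal(disjoint[["1"]], c("A", "B", "C"))
})

test_that("community-aligned synthetic terms are recovered in exactly one module", {
  pn <- generate_benchmark(benchmark_config(n = 300, mu = 0.05, d_avg = 10,
                                            d_max = 20, k_min = 30, k_max = 60,
                                            seed = 31))
  ann <- synthetic_annotations(pn, terms_per_community = 1, coverage = 0.8,
                               noise = 0, seed = 31)
  expect_identical(ann, synthetic_annotations(pn, terms_per_community = 1,
                                              coverage = 0.8, noise = 0, seed = 31))
  res <- bonferroni_filter(fisher_enrichment(pn$truth, ann), alpha = 0.001)
  aligned <- grep("^C", unique(res$term), value = TRUE)
  sig <- res[res$significant, ]
  for (term in aligned) {
    expect_equal(sum(sig$term == term), 1, info = term)
  }
  # noise = 0, coverage = 1 reproduces each community exactly
  ann1 <- synthetic_annotations(pn, coverage = 1, noise = 0, seed = 1)
  comms <- communities(pn$truth)
  for (ci in names(comms)) {
    expect_setequal(ann1$terms[[sprintf("C%s_t1", ci)]], comms[[ci]])
  }
})

test_that("shuffled null annotations produce (almost) no significant hits", {
  pn <- generate_benchmark(benchmark_config(n = 200, mu = 0.1, d_avg = 8,
                                            d_max = 15, k_min = 25, k_max = 50,
                                            seed = 8))
  nodes <- names(pn$truth)
  hits <- 0
  for (run in 1:20) {
    set.seed(run)
    shuffled <- setNames(unname(pn$truth), sample(nodes))
    ann <- synthetic_annotations(pn, coverage = 0.8, noise = 0, seed = run)
    # break the gene-term alignment by shuffling the partition's labels
    res <- bonferroni_filter(fisher_enrichment(shuffled, ann), alpha = 0.001)
    hits <- hits + sum(res$significant)
  }
  expect_lte(hits, 1)  # discrete hypergeometric tails are conservative under the null
})
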