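de_fixture <- function(n = 100, f = 50, n_sig = 0, shift = 2, seed = 1) {
  set.seed(seed)
  labels <- setNames(rep(1:2, length.out = n), sprintf("S%03d", 1:n))
  x <- matrix(rnorm(n * f), n, f,
              dimnames = list(names(labels), sprintf("F%03d", 1:f)))
  if (n_sig > 0)
    x[, 1:n_sig] <- x[, 1:n_sig] +
      outer(ifelse(labels == 1, shift / 2, -shift / 2), rep(1, n_sig))
  list(x = x, labels = labels)
}

test_that("null features show nominal type-I error and uniform p-values", {
  d <- de_fixture(n = 200, f = 2000, n_sig = 0, seed = 10)
  de <- differential_expression(d$x, d$labels)
  expect_gte(mean(de$p < 0.05), 0.04)
  expect_lte(mean(de$p < 0.05), 0.06)
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
  expect_false(any(de$significant))
})

test_that("a separable feature is significant with the right direction", {
  d <- de_fixture(n = 60, f = 20, seed = 3)
  d$x[, 1] <- ifelse(d$labels == 1, 1, 0) + rnorm(60, 0, 0.01)
  de <- differential_expression(d$x, d$labels)
  expect_lt(de$q[de$feature == "F001"], 1e-10)
  expect_identical(de$direction[de$feature == "F001"], "up")
  # down-regulation labelled from the subtype-1-minus-subtype-2 sign
  d$x[, 2] <- ifelse(d$labels == 1, -1, 0) + rnorm(60, 0, 0.01)
  de2 <- differential_expression(d$x, d$labels)
  expect_identical(de2$direction[de2$feature == "F002"], "down")
})

test_that("BH keeps the realized FDR controlled on mixed simulations", {
  fdp <- vapply(1:20, function(seed) {
    d <- de_fixture(n = 100, f = 1000, n_sig = 100, shift = 1.5, seed = seed)
    de <- differential_expression(d$x, d$labels)
    called <- de$feature[de$significant]
    if (length(called) == 0) return(0)
    truth <- sprintf("F%03d", 1:100)
    mean(!(called %in% truth))
  }, 0)
  expect_lte(mean(fdp), 0.05)
})

test_that("covariate adjustment leaves estimates unchanged when independent", {
  d <- de_fixture(n = 150, f = 200, n_sig = 20, seed = 8)
  set.seed(9)
  cov <- data.frame(cpi = rnorm(150, 50, 10))
  de0 <- differential_expression(d$x, d$labels)
  de1 <- differential_expression(d$x, d$labels, covariates = cov)
  expect_equal(de1$estimate, de0$estimate, tolerance = 0.1)
  expect_gt(cor(de1$estimate, de0$estimate), 0.99)
})

test_that("q-values order features identically to p-values within a modality", {
  d <- de_fixture(n = 80, f = 300, n_sig = 30, seed = 12)
  de <- differential_expression(d$x, d$labels)
  expect_identical(order(de$p), order(de$q, de$p))
  # up/down partition never overlaps
  expect_false(any(de$direction[!is.na(de$direction)] == "up" &
                   de$direction[!is.na(de$direction)] == "down"))
  sig <- de[de$significant, ]
  expect_true(all(sig$direction %in% c("up", "down")))
})

test_that("degenerate DE inputs are handled per contract", {
  d <- de_fixture(n = 30, f = 10, seed = 2)
  d$x[, 3] <- 5  # zero variance: skipped, not fatal
  de <- suppressMessages(differential_expression(d$x, d$labels))
  expect_false("F003" %in% de$feature)
  singleton <- d$labels; singleton[2:30] <- 2L
  expect_error(differential_expression(d$x, singleton), "singleton")
})

test_that("miRNA target expansion takes unions and logs unmapped miRNAs", {
  de <- data.frame(feature = c("m1", "m2", "m3", "m4"),
                   modality = "mirna",
                   estimate = c(1, 1, -1, -1), p = 0, q = 0,
                   significant = c(TRUE, TRUE, TRUE, FALSE),
                   direction = c("up", "up", "down", NA),
                   stringsAsFactors = FALSE)
  map <- list(m1 = c("A", "B"), m2 = c("B", "C"), m3 = c("D"))
  out <- map_mirna_targets(de, map)
  expect_identical(out$up, c("A", "B", "C"))
  expect_identical(out$down, "D")
  expect_identical(out$n_unmapped, 0L)
  out2 <- suppressMessages(map_mirna_targets(de, map[c("m1", "m3")]))
  expect_identical(out2$up, c("A", "B"))
  expect_identical(out2$n_unmapped, 1L)
  de0 <- de; de0$significant <- FALSE; de0$direction <- NA
  out0 <- map_mirna_targets(de0, map)
  expect_length(out0$up, 0)
  expect_length(out0$down, 0)
  expect_error(map_mirna_targets(de, list()), "empty")
})

test_that("hypergeometric ORA matches exhaustive enumeration", {
  # closed-form worked example: N=20, K=10, m=5, k=5
  coll <- gene_set_collection(list(path = sprintf("g%02d", 1:10)),
                              universe = sprintf("g%02d", 1:20))
  res <- ora_hypergeometric(sprintf("g%02d", 1:5), coll)
  expect_equal(res$p, 252 / 15504, tolerance = 1e-12)
  # k = 0 -> p = 1
  res0 <- ora_hypergeometric(sprintf("g%02d", 11:15), coll)
  expect_equal(res0$p, 1)
  # exhaustive enumeration over all m-subsets for several (N, K, m)
  for (spec in list(c(10, 4, 3), c(15, 6, 4), c(20, 10, 5), c(25, 8, 5))) {
    N <- spec[1]; K <- spec[2]; m <- spec[3]
    genes <- sprintf("u%02d", 1:N)
    coll2 <- gene_set_collection(list(s = genes[1:K]), universe = genes)
    subsets <- combn(N, m)
    overlaps <- colSums(subsets <= K)
    for (query_k in 0:min(K, m)) {
      query <- genes[c(seq_len(query_k),
                       K + seq_len(m - query_k))]
      p_enum <- mean(overlaps >= query_k)
      p_pkg <- ora_hypergeometric(query, coll2)$p
      expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    }
  }
})

test_that("ORA p is monotone when a pathway gene joins the query", {
  genes <- sprintf("u%02d", 1:20)
  coll <- gene_set_collection(list(s = genes[1:8]), universe = genes)
  for (base_k in 0:4) {
    q1 <- genes[c(seq_len(base_k), 9:12)]
    q2 <- c(q1, genes[base_k + 1])   # add one pathway gene
    expect_lte(ora_hypergeometric(q2, coll)$p,
               ora_hypergeometric(q1, coll)$p + 1e-12)
  }
})

test_that("ORA handles empty queries, outside genes, and empty collections", {
  coll <- gene_set_collection(list(s = c("a", "b")), universe = c("a", "b", "c"))
  expect_identical(nrow(ora_hypergeometric(character(), coll)), 0L)
  expect_warning(res <- ora_hypergeometric(c("a", "zz"), coll), "outside")
  expect_identical(res$overlap, 1L)
  expect_error(gene_set_collection(list()), "empty")
  expect_error(ora_hypergeometric("a", list(sets = list())), "gene_set_collection")
})

test_that("GMT round-trip and universe clipping", {
  sets <- list(P1 = c("a", "b", "c"), P2 = c("b", "d"))
  path <- withr::local_tempfile(fileext = ".gmt")
  snfsubtypes:::write_gmt(sets, path)
  coll <- read_gene_sets(path)
  expect_setequal(coll$universe, c("a", "b", "c", "d"))
  expect_identical(sort(coll$sets$P1), c("a", "b", "c"))
  clipped <- suppressMessages(gene_set_collection(sets, universe = c("a", "b", "d")))
  expect_identical(sort(clipped$sets$P1), c("a", "b"))
})

test_that("enrichment overlap produces the full Venn partition", {
  out <- enrichment_overlap(list(x = c("A", "B"), y = c("B", "C"), z = "B"))
  get <- function(region) out$n[out$region == region]
  expect_identical(get("x,y,z"), 1L)  # B
  expect_identical(get("x"), 1L)      # A
  expect_identical(get("y"), 1L)      # C
  expect_identical(get("x,y"), 0L)
  # disjoint and identical sets
  dis <- enrichment_overlap(list(x = "A", y = "B"))
  expect_identical(dis$n[dis$region == "x,y"], 0L)
  idt <- enrichment_overlap(list(x = c("A", "B"), y = c("A", "B")))
  expect_identical(idt$n[idt$region == "x,y"], 2L)
  expect_identical(sum(idt$n) , 2L)
  expect_error(enrichment_overlap(list(x = "A")), ">= 2")
  expect_error(enrichment_overlap(setNames(list("A", "B"), c("x", "x"))),
               "unique")
})
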