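test_that("joint collections are split into individual contributors", {
  expect_equal(disaggregate_collectors("Torre"), "Torre")
  expect_equal(disaggregate_collectors("Barbosa & Lemos"),
               c("Barbosa", "Lemos"))
  expect_equal(disaggregate_collectors("Kirk; Peters and Torre"),
               c("Kirk", "Peters", "Torre"))
  expect_equal(disaggregate_collectors(""), character(0))
  expect_equal(disaggregate_collectors(NA_character_), character(0))
  # word delimiters respect boundaries: "Anderson" is one person
  expect_equal(disaggregate_collectors("Anderson"), "Anderson")
})

test_that("collector metrics count specimens, provinces and activity span", {
  one <- make_records(1, collectors_raw = "Smith", collection_year = 1900L,
                      province = "Maputo")
  m <- collector_metrics(one)
  expect_equal(m[, c("nesp", "nlocality", "duration")],
               data.frame(nesp = 1, nlocality = 1L, duration = 0))

  # a long-career collector: specimens in 1934 and 1968 -> span 34 years
  torre <- make_records(2, collectors_raw = "Torre",
                        accepted_name = c("Genus a", "Genus b"),
                        collection_year = c(1934L, 1968L))
  expect_equal(collector_metrics(torre)$duration, 34)

  # joint collections credit each co-collector fully by default
  joint <- make_records(1, collectors_raw = "Barbosa & Lemos")
  mj <- collector_metrics(joint)
  expect_equal(mj$nesp, c(1, 1))
  mf <- collector_metrics(joint, credit = "fractional")
  expect_equal(mf$nesp, c(0.5, 0.5))
})

test_that("metrics equal a brute-force recount on a synthetic history", {
  syn <- simulate_collection_history(synthetic_truth(seed = 13),
                                     n_collectors = 12, n_specimens = 120)
  m <- collector_metrics(syn)
  # independent recount: simple split on the generator's single-name format
  tally <- new.env()
  for (i in seq_len(nrow(syn))) {
    nm <- tolower(trimws(syn$collectors_raw[i]))
    rec <- get0(nm, tally, ifnotfound = list(n = 0, prov = character(0),
                                             yrs = integer(0)))
    rec$n <- rec$n + 1
    if (!is.na(syn$province[i])) rec$prov <- union(rec$prov, syn$province[i])
    if (!is.na(syn$collection_year[i])) rec$yrs <- c(rec$yrs, syn$collection_year[i])
    assign(nm, rec, tally)
  }
  for (i in seq_len(nrow(m))) {
    rec <- get(m$name[i], tally)
    expect_equal(m$nesp[i], rec$n)
    expect_equal(m$nlocality[i], length(rec$prov))
    expect_equal(m$duration[i],
                 if (length(rec$yrs) >= 2) max(rec$yrs) - min(rec$yrs) else 0)
  }
})

test_that("min-max normalisation maps to [0,1] with an all-zero degenerate case", {
  expect_equal(min_max_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(min_max_normalize(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(min_max_normalize(c(1, 2, 10)), c(0, 1 / 9, 1))
  expect_error(min_max_normalize(c(1, Inf)), "finite")
  expect_error(min_max_normalize(numeric(0)), "non-empty")
})

test_that("the importance index is the weighted sum of normalised metrics", {
  # rows engineered so collector A has normalised metrics (1, 0.5, 0)
  m <- data.frame(
    name = c("A", "B", "C"),
    nesp = c(5, 1, 3),
    nlocality = c(2, 1, 3),
    duration = c(0, 4, 2)
  )
  ci <- collector_importance(m)
  a <- ci[ci$name == "A", ]
  expect_equal(a$nesp_norm, 1)
  expect_equal(a$nlocality_norm, 0.5)
  expect_equal(a$duration_norm, 0)
  expect_equal(a$index, 0.5 * 1 + 0.3 * 0.5 + 0.2 * 0)  # 0.65

  # maximal in all three metrics -> index 1
  m2 <- data.frame(name = c("A", "B"), nesp = c(9, 1), nlocality = c(5, 1),
                   duration = c(30, 0))
  expect_equal(collector_importance(m2)$index[1], 1)

  # identical collectors -> all indices 0 (degenerate normalisation)
  m3 <- data.frame(name = c("A", "B"), nesp = 2, nlocality = 1, duration = 5)
  expect_equal(collector_importance(m3)$index, c(0, 0))

  expect_error(
    collector_importance(m, structure(c(nesp = 0.5, nlocality = 0.5,
                                        duration = 0.5),
                                      class = "index_weights")),
    "sum to 1"
  )
  expect_error(index_weights(0.7, 0.2, 0.2), "sum to 1")
})

test_that("the index is invariant under affine rescaling of a raw metric", {
  set.seed(42)
  m <- data.frame(name = sprintf("C%02d", 1:15),
                  nesp = sample(1:60, 15, TRUE),
                  nlocality = sample(1:10, 15, TRUE),
                  duration = sample(0:40, 15, TRUE))
  base <- collector_importance(m)
  m2 <- m
  m2$duration <- 3.7 * m2$duration + 11  # strictly increasing affine map
  again <- collector_importance(m2)
  expect_equal(again$index, base$index, tolerance = 1e-12)
  expect_equal(again$name, base$name)
})

test_that("the ranking is deterministic under row shuffling", {
  set.seed(9)
  m <- data.frame(name = sprintf("C%02d", 1:12),
                  nesp = sample(1:20, 12, TRUE),
                  nlocality = sample(1:5, 12, TRUE),
                  duration = sample(0:30, 12, TRUE))
  r1 <- collector_importance(m)
  r2 <- collector_importance(m[sample(nrow(m)), ])
  expect_identical(r1, r2)
})

test_that("rank stability under weight perturbation matches brute force", {
  # trivial cases
  m1 <- data.frame(name = "Solo", nesp = 3, nlocality = 1, duration = 4)
  expect_equal(weight_sensitivity(m1, deltas = 0.1)$agreement, 1)
  set.seed(8)
  m <- data.frame(name = sprintf("C%02d", 1:20),
                  nesp = sample(1:50, 20, TRUE),
                  nlocality = sample(1:8, 20, TRUE),
                  duration = sample(0:40, 20, TRUE))
  expect_equal(weight_sensitivity(m, deltas = numeric(0))$agreement, 1)

  # delta = 0.05, 3^3 grid, against direct recomputation
  ws <- weight_sensitivity(m, deltas = 0.05)
  offs <- c(-0.05, 0, 0.05)
  top_default <- sort(collector_importance(m)$name[1:10])
  hits <- 0; total <- 0
  for (d1 in offs) for (d2 in offs) for (d3 in offs) {
    w <- c(0.5 + d1, 0.3 + d2, 0.2 + d3); w <- w / sum(w)
    norm <- function(v) (v - min(v)) / (max(v) - min(v))
    idx <- w[1] * norm(m$nesp) + w[2] * norm(m$nlocality) + w[3] * norm(m$duration)
    ord <- order(-idx, -m$nesp, m$name)
    hits <- hits + identical(sort(m$name[ord][1:10]), top_default)
    total <- total + 1
  }
  expect_equal(ws$n_grid, 27)
  expect_equal(ws$agreement, hits / total)
  expect_error(weight_sensitivity(m, deltas = 0.25), "smaller")
})

test_that("Spearman correlation matches rank-then-Pearson with exact and t p-values", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)

  s <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, stats::cor(rank(c(1, 2, 2, 4)), rank(c(1, 3, 2, 4))),
               tolerance = 1e-12)
  expect_equal(s$method, "exact permutation")

  # property: rho == cor of average ranks, 100 random tables
  set.seed(77)
  for (k in 1:100) {
    n <- sample(10:40, 1)
    x <- sample(1:8, n, TRUE); y <- x + stats::rnorm(n)
    got <- spearman_cor(x, y)
    expect_equal(got$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  }

  # t-approximation agrees with the reference implementation (no ties)
  set.seed(3)
  x <- stats::rnorm(25); y <- 0.4 * x + stats::rnorm(25)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)

  # exact permutation p agrees with full enumeration on a tiny case
  got5 <- spearman_cor(c(3, 1, 4, 2, 5), c(2, 1, 5, 3, 4))
  ref5 <- stats::cor.test(c(3, 1, 4, 2, 5), c(2, 1, 5, 3, 4),
                          method = "spearman", exact = TRUE)
  expect_equal(got5$p_value, ref5$p.value, tolerance = 1e-12)

  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("heatmap counts tally specimens per collector by decade and province", {
  ds <- make_records(4,
    collectors_raw = c("Kirk", "Kirk", "Kirk & Peters", "Peters"),
    collection_year = c(1861L, 1868L, 1889L, NA),
    province = c("Tete", "Tete", "Sofala", "Sofala")
  )
  hd <- collector_heatmap(ds, by = "decade")
  expect_equal(hd$n[hd$name == "kirk" & hd$decade == "1860"], 2)
  expect_equal(sum(hd$n[hd$name == "peters"]), 1)  # NA-year record omitted
  hp <- collector_heatmap(ds, by = "province")
  expect_equal(hp$n[hp$name == "kirk" & hp$province == "Tete"], 2)
  expect_equal(sum(hp$n), 5)  # joint collection credited twice
})
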