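test_that("AL is the signed day lag and is antisymmetric", {
  expect_equal(al_index(100, 90), 10)    # birds after insects: delayed
  expect_equal(al_index(90, 100), -10)   # birds before insects: asynchrony
  set.seed(2)
  a <- sample(1:200, 50); b <- sample(1:200, 50)
  expect_equal(al_index(a, b), -al_index(b, a))
})

test_that("AL' standardisation maps the pool onto [0, 1] affinely", {
  pool <- c(-20, 0, 20)
  expect_equal(standardize_al(0, pool), 0.5)
  expect_equal(standardize_al(-20, pool), 0)
  expect_equal(standardize_al(20, pool), 1)
  # affine invariance of the whole pool
  set.seed(4)
  p <- rnorm(30, 0, 15)
  expect_equal(standardize_al(p, p), standardize_al(2 * p + 5, 2 * p + 5))
  expect_error(standardize_al(1, c(3, 3)), "degenerate")
  expect_error(standardize_al(1, 3), "degenerate")
})

test_that("synchrony classification is inclusive at the 0.5 boundary", {
  expect_equal(classify_sync(0.49), "A")
  expect_equal(classify_sync(0.5), "S")
  expect_equal(classify_sync(0.7), "S")
  expect_error(classify_sync(1.2), "\\[0, 1\\]")
  # QAI is the character-wise concatenation of the two labels
  expect_equal(qai(0.6, 0.7), "SS")
  expect_equal(qai(0.3, 0.8), "AS")
  set.seed(6)
  x <- runif(40); y <- runif(40)
  expect_equal(qai(x, y), paste0(classify_sync(x), classify_sync(y)))
})

test_that("the packaged roster reproduces the case-study composition", {
  r <- species_roster()
  expect_equal(unname(table(r$group)[c("bird", "butterfly", "moth",
                                       "vegetation")]),
               c(5L, 9L, 9L, 7L), ignore_attr = TRUE)
  expect_false(any(duplicated(r$code)))
  expect_true(all(r$trophic_level[r$group == "bird"] == 3))
  expect_true(all(r$trophic_level[r$group %in%
                                    c("butterfly", "moth")] == 2))
  expect_true(all(r$trophic_level[r$group == "vegetation"] == 1))
  p <- enumerate_pairs(r)
  expect_equal(nrow(p), 251L)
  tab <- table(p$pair_class)
  expect_equal(unname(tab[c("3-2", "2-1", "3-1")]), c(90L, 126L, 35L),
               ignore_attr = TRUE)
})

test_that("WO composite sums the per-variable bird-insect differences", {
  b <- c(TMIN = 60, TMAX = 60, TPPT = 60)
  i <- c(TMIN = 50, TMAX = 50, TPPT = 50)
  expect_equal(as.numeric(wo_composite(b, b)), 0)
  expect_equal(as.numeric(wo_composite(b, i)), 30)
  expect_equal(as.numeric(wo_composite(i, b)), -30)  # antisymmetry
  b2 <- c(TMIN = 60, TMAX = NA, TPPT = 60)
  expect_error(wo_composite(b2, i), "TMAX")
  dropped <- wo_composite(b2, i, drop_missing = TRUE)
  expect_equal(as.numeric(dropped), 20)
  expect_equal(attr(dropped, "variables_used"), c("TMIN", "TPPT"))
})

test_that("IICWM categories partition the sign quadrants", {
  expect_equal(iicwm(10, 20), data.frame(value = 0.5, category = "+"))
  # identical positive ratio but scenario B: the asterisk case
  expect_equal(iicwm(-10, -20), data.frame(value = 0.5, category = "*"))
  expect_equal(iicwm(-10, 20)$category, "-")
  expect_equal(iicwm(10, -20)$category, "-")
  expect_error(iicwm(5, 0), "undefined ratio")
  # total partition: every nonzero-wo input gets exactly one symbol
  set.seed(8)
  al <- rnorm(200, 0, 30)
  wo <- sample(c(-1, 1), 200, TRUE) * runif(200, 0.5, 90)
  cat <- iicwm(al, wo)$category
  expect_true(all(cat %in% c("+", "-", "*")))
  expect_equal(cat == "+", al >= 0 & wo > 0)
  expect_equal(cat == "*", al < 0 & wo < 0)
})

test_that("al_scores builds the cross-trophic table with pooling", {
  sums <- data.frame(species = c("BS", "GW", "BM", "RI", "OAH", "BW"),
                     year = 2015,
                     median = c(110, 120, 95, 100, 64, 70))
  sums <- rbind(sums, transform(sums, year = 2016,
                                median = median + c(5, -5, 0, 10, 2, -2)))
  sc <- al_scores(sums)
  expect_equal(nrow(sc), (2 * 2 + 2 * 2 + 2 * 2) * 2)
  bs_bm_15 <- sc[sc$species_hi == "BS" & sc$species_lo == "BM" &
                   sc$year == 2015, ]
  expect_equal(bs_bm_15$al, 110 - 95)
  expect_true(all(sc$al_prime >= 0 & sc$al_prime <= 1))
  # within each pair class the extremes hit exactly 0 and 1
  for (cls in unique(sc$pair_class)) {
    ap <- sc$al_prime[sc$pair_class == cls]
    expect_equal(min(ap), 0); expect_equal(max(ap), 1)
  }
  # per-species-pair pooling maps every pair's own range to [0, 1]
  sc2 <- al_scores(sums, pool = "species_pair")
  expect_true(all(sc2$al_prime %in% c(0, 1)))  # two years per pair
})

test_that("networks split pairs at 0.5 with the documented weights", {
  scores <- data.frame(
    species_hi = c("BS", "GW", "NW", "SW"),
    species_lo = c("BM", "BM", "BM", "BM"),
    pair_class = "3-2", year = 2015,
    al = c(-30, 0, 10, 30),
    al_prime = c(0, 0.5, 0.75, 1))
  sync <- build_network(scores, "sync")
  async <- build_network(scores, "async")
  expect_equal(sync$edges$source, c("GW", "NW", "SW"))
  expect_equal(sync$edges$weight, c(1, 0.5, 0))   # 0.5 is total synchrony
  expect_equal(async$edges$source, "BS")
  expect_equal(async$edges$weight, 1)             # 0 is total asynchrony
  # partition: each pair appears in exactly one network
  both <- c(paste(sync$edges$source, sync$edges$target),
            paste(async$edges$source, async$edges$target))
  expect_equal(sort(both), sort(paste(scores$species_hi,
                                      scores$species_lo)))
  # GraphML round-trips through igraph
  tmp <- tempfile(fileext = ".graphml")
  write_network_graphml(sync, tmp)
  g <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
})

test_that("tally_classifications counts categories and full synchrony", {
  t <- tally_classifications()
  expect_equal(t$categories, c(`+` = 12L, `-` = 42L, `*` = 36L))
  expect_equal(t$fully_synchronous, 17L)
  empty <- iicwm_classifications()[0, ]
  t0 <- tally_classifications(empty)
  expect_equal(unname(t0$categories), c(0L, 0L, 0L))
  expect_equal(t0$fully_synchronous, 0L)
  bad <- iicwm_classifications(); bad$iicwm[1] <- "x"
  expect_error(tally_classifications(bad), "schema")
})
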