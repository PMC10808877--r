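test_that("nearest_pairs builds the de-duplicated k-neighbour pair set", {
  soc3 <- tibble::tibble(id = c("a", "b", "c"), lat = c(0, 1, 2), lon = 0)
  expect_equal(nrow(nearest_pairs(soc3, k = 100)), 3)   # complete graph

  # k = 1 on equally spaced collinear points: adjacency pairs only
  soc5 <- tibble::tibble(id = sprintf("s%d", 1:5), lat = (0:4) * 2, lon = 0)
  p1 <- nearest_pairs(soc5, k = 1)
  expect_true(all(paste(p1$id_A, p1$id_B) %in%
                    c("s1 s2", "s2 s3", "s3 s4", "s4 s5")))

  set.seed(4)
  soc <- tibble::tibble(id = sprintf("s%02d", 1:40),
                        lat = runif(40, -30, 30), lon = runif(40, 0, 40))
  k <- 7
  p <- nearest_pairs(soc, k = k)
  expect_lte(nrow(p), 40 * k)
  expect_gte(nrow(p), 40 * k / 2)
  expect_true(all(p$id_A < p$id_B))
  expect_false(any(duplicated(paste(p$id_A, p$id_B))))

  # row count invariant to input ordering
  p_shuf <- nearest_pairs(soc[sample(40), ], k = k)
  expect_equal(nrow(p_shuf), nrow(p))
})

test_that("sharing is scored on recoded codes with absence semantics", {
  tt <- tibble::tibble(
    society_id = c("a", "b", "c", "d", "e", "f", "g"),
    trait_id = "agri",
    code = c("casual", "intensive", "none", "extensive", NA,
             "herding", "fishing"))
  rc <- suppressMessages(recode_traits(
    tt, recoding = list(agri = c(casual = "AGRI", extensive = "AGRI",
                                 intensive = "AGRI")),
    absent_code = "none"))
  pairs <- tibble::tibble(id_A = c("a", "a", "a", "a"),
                          id_B = c("b", "c", "d", "e"))
  sc <- score_sharing(pairs, rc, "agri")
  # casual + intensive both recode to AGRI -> share
  expect_equal(sc$share, c(1L, NA_integer_, 1L, NA_integer_))

  tt2 <- tibble::tibble(society_id = c("a", "b"), trait_id = "t",
                        code = c(3, 5))
  sc2 <- score_sharing(tibble::tibble(id_A = "a", id_B = "b"),
                       suppressMessages(recode_traits(
                         dplyr::bind_rows(tt2,
                                          tibble::tibble(society_id = "c",
                                                         trait_id = "t",
                                                         code = 7)))), "t")
  expect_equal(sc2$share, 0L)
  expect_error(score_sharing(pairs, rc, "nope"), "unknown trait")
})

test_that("traits reduced to two or fewer categories are rejected at the table level", {
  tt <- tibble::tibble(
    society_id = rep(c("a", "b", "c", "d"), 2),
    trait_id = rep(c("t1", "t2"), each = 4),
    code = c(1, 2, 3, 1,      # t1: 3 categories -> kept
             1, 2, 1, 2))     # t2: 2 categories -> dropped
  expect_message(rc <- recode_traits(tt), "t2")
  expect_equal(attr(rc, "dropped_traits"), "t2")
  expect_false("t2" %in% rc$trait_id)

  # recoding can itself collapse a trait under the threshold
  tt3 <- tibble::tibble(society_id = c("a", "b", "c"), trait_id = "t3",
                        code = c("x", "y", "z"))
  expect_message(rc3 <- recode_traits(tt3, recoding = list(t3 = c(x = "y"))),
                 "t3")
  expect_false("t3" %in% rc3$trait_id)
})

test_that("relatedness equals hand-computed patristic distances", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  pr <- tibble::tibble(id_A = c("A", "A", "B"), id_B = c("B", "C", "C"))
  r <- relatedness(pr, tr)
  expect_equal(r$relatedness, c(2, 6, 6))

  # missing tip flagged, not errored
  pr2 <- tibble::tibble(id_A = "A", id_B = "Z")
  r2 <- relatedness(pr2, tr)
  expect_true(is.na(r2$relatedness))
  expect_equal(r2$relatedness_reason, "tip_missing")

  # ultrametric identity: distance = 2 x MRCA age
  tru <- simulate_tree(12, seed = 3)
  cd <- ape::cophenetic.phylo(tru)
  depths <- ape::node.depth.edgelength(tru)
  mrca_all <- ape::mrca(tru)
  total <- max(depths)
  for (pair in list(c(1, 5), c(2, 9), c(3, 12))) {
    age <- total - depths[mrca_all[pair[1], pair[2]]]
    expect_equal(unname(cd[pair[1], pair[2]]), 2 * age, tolerance = 1e-10)
  }
})

test_that("patristic distances satisfy the four-point condition on random quartets", {
  tr <- simulate_tree(20, seed = 6)
  cd <- ape::cophenetic.phylo(tr)
  set.seed(8)
  for (i in 1:25) {
    q <- sample(rownames(cd), 4)
    s1 <- cd[q[1], q[2]] + cd[q[3], q[4]]
    s2 <- cd[q[1], q[3]] + cd[q[2], q[4]]
    s3 <- cd[q[1], q[4]] + cd[q[2], q[3]]
    srt <- sort(c(s1, s2, s3))
    expect_lte(srt[3] - srt[2], 1e-8)   # two largest sums are equal
  }
})

# 12-society line fixture: society sXX sits at lat = XX * 0.1; trait values
# chosen so the directional neighbourhood proportions are known by hand.
nt_fixture <- function() {
  soc <- tibble::tibble(id = sprintf("s%02d", 1:12),
                        lat = (1:12) * 0.1, lon = 0)
  # pair (s03, s10). A = s03: nearest others are s02,s04,s01,s05,s06,...
  # B = s10: nearest others are s09,s11,s08,s12,s07,...
  codes <- c(s01 = "x", s02 = "x", s03 = "q", s04 = "y", s05 = "x",
             s06 = "z", s07 = "x", s08 = "y", s09 = "y",
             s10 = "x", s11 = "z", s12 = "y")
  tt <- tibble::tibble(society_id = names(codes), trait_id = "t",
                       code = unname(codes), absent = FALSE)
  list(soc = soc, tt = tt)
}

test_that("neighbour transmission averages the two directional proportions", {
  fx <- nt_fixture()
  pr <- tibble::tibble(id_A = "s03", id_B = "s10")
  # A side: 5 nearest with data (excluding s03 and s10) = s02,s04,s01,s05,s06
  #   values x,y,x,x,z; B value = x -> 3/5 = 0.6
  # B side: 5 nearest = s09,s11,s08,s12,s07 values y,z,y,y,x; A value = q -> 0
  # hand value: (0.6 + 0.0) / 2 = 0.3
  v <- neighbor_transmission(pr, fx$soc, fx$tt, "t", mode = "five_with_data")
  expect_equal(v$neighbor_trans, 0.3)

  # all neighbours share B's value on both sides -> 1.0
  tt_all <- fx$tt
  tt_all$code <- "x"
  v1 <- neighbor_transmission(pr, fx$soc, tt_all, "t", mode = "five_with_data")
  expect_equal(v1$neighbor_trans, 1)
})

test_that("the ten-neighbour mode enforces the 3-of-10 retention rule", {
  fx <- nt_fixture()
  pr <- tibble::tibble(id_A = "s03", id_B = "s10")
  v <- neighbor_transmission(pr, fx$soc, fx$tt, "t", mode = "ten_any")
  expect_false(is.na(v$neighbor_trans))

  # strip data until only 2 of A's 10 nearest have data -> pair dropped
  tt2 <- fx$tt
  tt2$code[!(tt2$society_id %in% c("s01", "s02", "s03", "s10"))] <- NA
  v2 <- neighbor_transmission(pr, fx$soc, tt2, "t", mode = "ten_any")
  expect_true(is.na(v2$neighbor_trans))
})

test_that("neighbour transmission is invariant to relabelling trait codes", {
  fx <- nt_fixture()
  pr <- tibble::tibble(id_A = c("s03", "s05"), id_B = c("s10", "s08"))
  v1 <- neighbor_transmission(pr, fx$soc, fx$tt, "t")
  perm <- c(x = "B", y = "C", z = "A", q = "D")
  tt2 <- fx$tt
  tt2$code <- unname(perm[tt2$code])
  v2 <- neighbor_transmission(pr, fx$soc, tt2, "t")
  expect_equal(v1$neighbor_trans, v2$neighbor_trans)
  expect_true(all(v1$neighbor_trans >= 0 & v1$neighbor_trans <= 1,
                  na.rm = TRUE))
})

test_that("assemble_pair_covariates returns complete 11-predictor rows", {
  cfg <- tiny_config(n_societies = 25, mu_vertical = 1)
  w <- suppressMessages(simulate_world(cfg, n_traits = 2))
  pairs <- nearest_pairs(w$societies, k = 6)
  b <- suppressMessages(pair_barriers(pairs, w$societies, w$env,
                                      w$elevation, w$graph))
  tt <- suppressMessages(recode_traits(w$traits))
  tr <- tt$trait_id[1]
  df <- suppressMessages(assemble_pair_covariates(pairs, b, w$societies, tt,
                                                  w$tree, tr))
  expect_true(all(c("share", "th_dissim", "relatedness", "neighbor_trans")
                  %in% names(df)))
  expect_equal(ncol(df), 14)   # 2 ids + share + 11 predictors
  expect_false(any(is.na(df)))
})
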