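g5 <- make_grid(0.5, 0.05, 0.05)

mk_map <- function(year, ...) {
  turf_map("t", year, g5, data.frame(...))
}

test_that("identical maps yield in-place survivals only", {
  m1 <- mk_map(2017, taxon = c("a", "a", "b"), row = c(2, 4, 2),
               col = c(2, 4, 3), cover_cm2 = c(5, 3, 7))
  m2 <- mk_map(2018, taxon = c("a", "a", "b"), row = c(2, 4, 2),
               col = c(2, 4, 3), cover_cm2 = c(5, 3, 7))
  rec <- link_years(m1, m2, 1)
  expect_equal(sort(unique(rec$event)), "survival")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$size_to_cm2 - rec$size_from_cm2, rep(0, 3))
  expect_equal(rec$row_from, rec$row_to)
})

test_that("disappearance is a death, appearance a recruit", {
  m1 <- mk_map(2017, taxon = "a", row = 3, col = 3, cover_cm2 = 4)
  m2 <- mk_map(2018, taxon = "b", row = 6, col = 6, cover_cm2 = 2)
  rec <- link_years(m1, m2, 1)
  expect_equal(nrow(rec), 2)
  d <- rec[rec$event == "death", ]
  expect_equal(d$taxon, "a"); expect_true(is.na(d$size_to_cm2))
  r <- rec[rec$event == "recruit", ]
  expect_equal(r$taxon, "b"); expect_true(is.na(r$size_from_cm2))
})

test_that("displacement radius decides move vs death+recruit", {
  m1 <- mk_map(2017, taxon = "a", row = 3, col = 3, cover_cm2 = 4)
  m2 <- mk_map(2018, taxon = "a", row = 3, col = 4, cover_cm2 = 4.5)
  rec1 <- link_years(m1, m2, max_displacement_quadrants = 1)
  expect_equal(rec1$event, "survival")
  expect_equal(rec1$col_to, 4)
  rec0 <- link_years(m1, m2, max_displacement_quadrants = 0)
  expect_setequal(rec0$event, c("death", "recruit"))
})

test_that("link_years validates its inputs", {
  m1 <- mk_map(2017, taxon = "a", row = 3, col = 3, cover_cm2 = 4)
  m3 <- mk_map(2019, taxon = "a", row = 3, col = 3, cover_cm2 = 4)
  expect_error(link_years(m1, m3), "consecutive")
  other <- turf_map("u", 2018, g5,
                    data.frame(taxon = "a", row = 3, col = 3, cover_cm2 = 4))
  expect_error(link_years(m1, other), "share")
})

test_that("conservation holds on random consecutive maps", {
  k <- kernel_spec()
  withr::with_seed(21, {
    for (rep in 1:5) {
      m1 <- random_map(g5, 40, year = 2017L)
      m2 <- random_map(g5, 40, year = 2018L)
      rec <- link_years(m1, m2, 1)
      inner1 <- m1$cover[is_inner(g5, m1$cover$row, m1$cover$col), ]
      inner2 <- m2$cover[is_inner(g5, m2$cover$row, m2$cover$col), ]
      for (tx in union(inner1$taxon, inner2$taxon)) {
        rt <- rec[rec$taxon == tx, ]
        expect_equal(sum(inner1$taxon == tx),
                     sum(rt$event == "survival") + sum(rt$event == "death"))
        expect_equal(sum(inner2$taxon == tx),
                     sum(rt$event == "survival") + sum(rt$event == "recruit"))
      }
    }
  })
})

test_that("demography table batches series and annotates crowding", {
  base <- data.frame(taxon = c("a", "a", "b"), row = c(2, 4, 2),
                     col = c(2, 4, 2), cover_cm2 = c(5, 3, 7))
  maps <- lapply(2017:2019, function(y) turf_map("t", y, g5, base))
  tab <- build_demography_table(maps, kernel_spec())
  expect_equal(nrow(tab), 6) # 3 units x 2 transitions
  expect_true(all(tab$event == "survival"))
  # crowding annotated from the year-from map
  cr <- brute_crowding(maps[[1]], "a", 2, 2, kernel_spec())
  row_a <- tab[tab$taxon == "a" & tab$row_from == 2 & tab$year_from == 2017, ]
  expect_equal(row_a$w_con, cr$w_i, tolerance = 1e-12)
  expect_equal(row_a$w_het, cr$w_j, tolerance = 1e-12)

  # empty first year: everything is a recruit
  empty <- turf_map("t", 2017, g5,
                    data.frame(taxon = character(0), row = integer(0),
                               col = integer(0), cover_cm2 = numeric(0)))
  tab2 <- build_demography_table(list(empty, turf_map("t", 2018, g5, base)))
  expect_true(all(tab2$event == "recruit"))
  expect_equal(nrow(tab2), 3)

  # gap years warn and skip the missing transition
  gappy <- list(turf_map("t", 2017, g5, base), turf_map("t", 2019, g5, base))
  expect_warning(tab3 <- build_demography_table(gappy), "gap")
  expect_equal(nrow(tab3), 0)
})

test_that("recruitment trials cover exactly the unoccupied quadrants", {
  base <- data.frame(taxon = c("a", "b"), row = c(2, 3), col = c(2, 3),
                     cover_cm2 = c(5, 7))
  nxt <- data.frame(taxon = c("a", "b", "a"), row = c(2, 3, 5),
                    col = c(2, 3, 5), cover_cm2 = c(5, 7, 0.25))
  maps <- list(turf_map("t", 2017, g5, base), turf_map("t", 2018, g5, nxt))
  tr <- build_recruitment_table(maps, kernel_spec())
  n_inner <- g5$n_inner
  # per taxon: one trial per inner quadrant it did not occupy at year t
  expect_equal(sum(tr$taxon == "a"), n_inner - 1)
  expect_equal(sum(tr$taxon == "b"), n_inner - 1)
  expect_equal(sum(tr$recruited), 1)
  hit <- tr[tr$recruited == 1, ]
  expect_equal(hit$taxon, "a")
  expect_equal(c(hit$row, hit$col), c(5, 5))
  # no trial on an occupied quadrant
  expect_false(any(tr$taxon == "a" & tr$row == 2 & tr$col == 2))
})

test_that("tracking recovers generator ground truth", {
  # noiseless series: exact fate recovery with matching radius 0
  des <- synthetic_design(n_taxa = 4, n_turfs_per_site = 1,
                          site_offsets_K = c(0, 3.3),
                          displacement_rate = 0)
  gen <- generate_turf_series(des, seed = 5)
  rec <- build_demography_table(gen$maps, des$kernel, max_displacement = 0)
  expect_true(all(fate_key(gen$truth) %in% fate_key(rec)))
  expect_equal(nrow(rec), nrow(gen$truth))

  # displaced series: recovery degrades gracefully but stays high
  des1 <- synthetic_design(n_taxa = 4, n_turfs_per_site = 1,
                           site_offsets_K = c(0, 3.3))
  gen1 <- generate_turf_series(des1, seed = 5)
  rec1 <- build_demography_table(gen1$maps, des1$kernel,
                                 max_displacement = 1)
  acc <- mean(fate_key(gen1$truth) %in% fate_key(rec1))
  expect_gt(acc, 0.9)
})
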