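test_that("parameter sampling is seeded and respects its constraints", {
  des <- synthetic_design()
  p1 <- sample_taxon_params(des, seed = 4)
  p2 <- sample_taxon_params(des, seed = 4)
  expect_equal(p1, p2)
  expect_equal(length(p1), des$n_taxa)

  # warm-optimum taxon: growth peak 2-4 K above home by construction
  expect_gte(p1$warm_forb$growth$T_opt, des$T_home_C + 2)
  expect_lte(p1$warm_forb$growth$T_opt, des$T_home_C + 4)
  # cold decliner: optimum at or below home
  expect_lte(p1$cold_shrub$growth$T_opt, des$T_home_C)

  for (tp in p1) {
    expect_gt(tp$survival$k_sig, 0)
    expect_gt(tp$growth$sigma_T, 0)
    expect_gt(tp$growth$sigma_eps, 0)
    # recruitment coefficients alpha = exp(.) are positive at site climates
    for (Tv in des$T_home_C + des$site_offsets_K) {
      expect_gt(exp(tp$recruitment$r_ii0 + tp$recruitment$r_ii1 * Tv), 0)
      expect_gt(exp(tp$recruitment$r_ij0 + tp$recruitment$r_ij1 * Tv), 0)
    }
  }
})

test_that("generated series carry exact ground truth", {
  des <- synthetic_design(n_taxa = 4, n_turfs_per_site = 1,
                          site_offsets_K = c(0, 5.5))
  gen <- generate_turf_series(des, seed = 2)
  # conservation identities between the truth table and the maps
  for (tid in names(gen$maps)) {
    yrs <- as.integer(names(gen$maps[[tid]]))
    for (k in seq_len(length(yrs) - 1)) {
      m0 <- gen$maps[[tid]][[k]]; m1 <- gen$maps[[tid]][[k + 1]]
      tr <- gen$truth[gen$truth$turf_id == tid &
                        gen$truth$year_from == yrs[k], ]
      for (tx in unique(c(map_taxa(m0), map_taxa(m1)))) {
        n0 <- sum(m0$cover$taxon == tx &
                    is_inner(des$grid, m0$cover$row, m0$cover$col))
        n1 <- sum(m1$cover$taxon == tx &
                    is_inner(des$grid, m1$cover$row, m1$cover$col))
        tt <- tr[tr$taxon == tx, ]
        expect_equal(n0, sum(tt$event %in% c("survival", "death")))
        expect_equal(n1, sum(tt$event %in% c("survival", "recruit")))
      }
    }
  }
  # truth coordinates point at real units in the emitted maps
  sv <- gen$truth[gen$truth$event == "survival", ]
  for (i in sample(nrow(sv), 25)) {
    m1 <- gen$maps[[sv$turf_id[i]]][[as.character(sv$year_to[i])]]
    expect_true(any(m1$cover$taxon == sv$taxon[i] &
                      m1$cover$row == sv$row_to[i] &
                      m1$cover$col == sv$col_to[i]))
  }
})

test_that("default-seed dynamics match the stated transplant behaviour", {
  gen <- generate_turf_series(synthetic_design(), seed = 1)
  sites <- gen$turf_site
  change <- function(site) {
    tids <- names(sites)[sites == site]
    sapply(tids, function(tid) {
      covs <- sapply(gen$maps[[tid]], total_cover)
      covs[length(covs)] / covs[1] - 1
    })
  }
  # home-climate site: quasi-stable (< 20% total cover change in 4 years)
  expect_true(all(abs(change("site1")) < 0.2))
  # warmest site (+5.5 K): majority of taxa decline
  tids4 <- names(sites)[sites == "site4"]
  per_taxon <- sapply(names(gen$params), function(tx) {
    f <- function(y) sum(sapply(tids4, function(tid) {
      v <- total_cover(gen$maps[[tid]][[y]], by_taxon = TRUE)
      sum(v[tx], na.rm = TRUE)
    }))
    f(length(gen$maps[[tids4[1]]])) < f(1)
  })
  expect_gt(mean(per_taxon), 0.5)
})

test_that("fixture suites are byte-identical given the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  des <- synthetic_design(n_taxa = 3, n_turfs_per_site = 1,
                          site_offsets_K = c(0, 3.3), n_years = 3)
  make_fixture_suite(d1, seed = 6, design = des)
  make_fixture_suite(d2, seed = 6, design = des)
  files <- c("maps.csv", "climate.csv", "true_params.json",
             "true_demography.csv", "config.yaml")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("the fixture suite drives the whole pipeline end to end", {
  dir <- withr::local_tempdir()
  des <- synthetic_design(n_taxa = 3, n_turfs_per_site = 1,
                          site_offsets_K = c(0, 5.5), n_years = 4,
                          displacement_rate = 0)
  gen <- make_fixture_suite(dir, seed = 8, design = des)
  cfg <- read_config(file.path(dir, "config.yaml"))
  maps <- read_turf_maps(file.path(dir, "maps.csv"), cfg$grid)
  climate <- read_climate(file.path(dir, "climate.csv"))
  truep <- read_params(file.path(dir, "true_params.json"))

  # track
  demog <- build_demography_table(maps, cfg$kernel)
  expect_gt(nrow(demog), 500)
  trials <- build_recruitment_table(maps, cfg$kernel)
  ts <- unlist(cfg$turf_site)
  demog <- attach_climate(demog, climate, ts)
  trials <- attach_climate(trials, climate, ts)

  # fit the most data-rich taxon
  taxa <- select_taxa(demog, min_obs = 300)
  expect_gt(length(taxa), 0)
  tx <- taxa[which.max(table(demog$taxon)[taxa])]
  fit <- fit_taxon(demog, trials, tx, seed = 1)
  expect_s3_class(fit$params, "taxon_params")
  expect_true(all(vapply(fit$fits, function(f)
    all(is.finite(f$internal)), logical(1))))

  # validate with the true (generating) parameters at the warm site
  warm_t <- names(gen$turf_site)[gen$turf_site == "site2"]
  init <- lapply(warm_t, function(t) gen$maps[[t]][["2017"]])
  fin <- lapply(warm_t, function(t) gen$maps[[t]][["2020"]])
  dom <- names(sort(sapply(names(truep), function(t)
    sum(sapply(init, function(m)
      sum(total_cover(m, by_taxon = TRUE)[t], na.rm = TRUE)))),
    decreasing = TRUE))[1]
  v <- validate_taxon(dom, truep, init, fin, climate$site2,
                      cfg$kernel, n_reps = 10, seed = 3)
  expect_true(is.finite(v$ssr_ratio))

  # simulate and summarise
  ens <- run_scenario(gen$maps[[1]][[1]],
                      constant_scenario(des$T_home_C, 6),
                      truep, cfg$kernel, n_reps = 3, seed = 4)
  wide <- matrix(ens$summary$median, ncol = length(ens$taxa),
                 dimnames = list(ens$years, ens$taxa))
  expect_s3_class(pcoa(wide), "ordination_result")
  expect_s3_class(compare_trajectories(list(ens)), "trajectory_report")
})
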