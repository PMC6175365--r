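test_that("wood specific gravity is the dry-mass to green-volume ratio", {
  expect_equal(wood_specific_gravity(0.75, 1.5), 0.5)
  expect_equal(wood_specific_gravity(3.7, 3.7), 1)
  expect_error(wood_specific_gravity(0, 1.5), "> 0")
  expect_error(wood_specific_gravity(1, -2), "> 0")
})

test_that("small stems inherit the plot mean wsg of large stems", {
  stems <- rbind(stem_rows(dbh = c(10, 20), wsg = c(0.4, 0.6)),
                 stem_rows(dbh = 3, size_class = "small"))
  out <- assign_small_stem_wsg(stems)
  expect_equal(out$wsg[out$size_class == "small"], 0.5)

  single <- rbind(stem_rows(dbh = 12, wsg = 0.55),
                  stem_rows(dbh = 2, size_class = "small"))
  expect_equal(assign_small_stem_wsg(single)$wsg[2], 0.55)

  orphan <- stem_rows(dbh = 3, size_class = "small")
  expect_error(assign_small_stem_wsg(orphan), "plot p1")
  expect_warning(out <- assign_small_stem_wsg(orphan, fallback = 0.57),
                 "fallback")
  expect_equal(out$wsg, 0.57)
})

test_that("tree ensemble is the mean over habitat-applicable equations", {
  reg <- toy_registry()
  # single equation B = 0.1 * (rho * D^2)^1 at D = 10, rho = 0.5
  expect_equal(tree_biomass_ensemble(10, 0.5, "secondary", reg), 5)
  expect_error(tree_biomass_ensemble(10, 0.5, "old_growth", reg),
               "no equations")
  expect_error(tree_biomass_ensemble(0.5, 0.5, "secondary", reg), ">= 1")

  # ensemble equals manual per-equation evaluation then averaging, and lies
  # inside the per-equation envelope
  for (hab in c("old_growth", "secondary")) {
    eqs <- default_registry[default_registry$habitat == hab, ]
    for (case in list(c(50, 0.6), c(7, 0.35), c(120, 0.8))) {
      each <- vapply(seq_len(nrow(eqs)), function(i)
        swidcarbon:::evaluate_equation(eqs[i, ], case[1], case[2]),
        numeric(1))
      ens <- tree_biomass_ensemble(case[1], case[2], hab, default_registry)
      expect_equal(ens, mean(each))
      expect_gte(ens, min(each))
      expect_lte(ens, max(each))
    }
  }
})

test_that("liana plot biomass averages the two subplot sums", {
  reg <- toy_registry()  # liana equation B = 0.05 * D^2
  rec <- data.frame(plot = "p1", subplot = c("V1", "V1", "V2"),
                    dbh = c(8, 4, 10))
  # V1: 0.05*64 + 0.05*16 = 4; V2: 0.05*100 = 5
  expect_equal(liana_plot_biomass(rec, reg), 4.5)
  # one liana in V1 only: (0.8 + 0)/2
  one <- data.frame(plot = "p1", subplot = "V1", dbh = 4)
  expect_equal(liana_plot_biomass(one, reg), 0.4)
  expect_equal(liana_plot_biomass(one[0, ], reg), 0)
  bad <- data.frame(plot = "p1", subplot = "V3", dbh = 4)
  expect_error(liana_plot_biomass(bad, reg), "V1 or V2")
})

test_that("frustum and cone volumes match the quadrature oracle", {
  expect_equal(frustum_volume(100, 6, 3), 2100 * pi)
  expect_equal(cone_volume(100, 6), 1200 * pi)
  # cylinder and cone limits
  expect_equal(frustum_volume(50, 4, 4), pi * 16 * 50)
  expect_equal(frustum_volume(100, 6, 1e-9), cone_volume(100, 6),
               tolerance = 1e-6)
  # independent quadrature over the linear taper
  expect_equal(frustum_volume(100, 6, 3), taper_volume_quadrature(100, 6, 3),
               tolerance = 1e-7)
  expect_equal(cone_volume(300, 5), taper_volume_quadrature(300, 5, 1e-12),
               tolerance = 1e-7)
  expect_error(frustum_volume(-1, 6, 3), "> 0")
  # monotone in every dimension
  set.seed(1)
  for (i in 1:20) {
    h <- runif(1, 1, 500); R <- runif(1, 1, 50); r <- runif(1, 0.1, R)
    v <- frustum_volume(h, R, r)
    expect_gt(frustum_volume(h * 1.1, R, r), v)
    expect_gt(frustum_volume(h, R * 1.1, r), v)
    expect_gt(frustum_volume(h, R, r * 1.1), v)
  }
})

test_that("deadwood biomass picks formula and density correctly", {
  tab <- default_decay
  # frustum: diameters 12/6 cm -> radii 6/3, x 0.5 g/cm3 measured
  expect_equal(deadwood_biomass(deadwood_row(), tab), 2100 * pi * 0.5 / 1000)
  # cone (no top diameter), class density 0.3
  tab3 <- structure(setNames(c(0.5, 0.4, 0.3, 0.2, 0.1), 1:5),
                    class = "decay_density_table")
  rec <- deadwood_row(posture = "standing", top = NA, class = 3,
                      density = NA)
  expect_equal(deadwood_biomass(rec, tab3), 1200 * pi * 0.3 / 1000)
  # class-1 record without a measured density
  rec1 <- deadwood_row(density = NA)
  expect_equal(deadwood_biomass(rec1, tab), 2100 * pi * tab[["1"]] / 1000)
  expect_error(deadwood_biomass(rec1, tab, use_table_fallback = FALSE),
               "measured density")
})

test_that("decay tables must be positive and non-increasing", {
  dir <- withr_local_tempdir()
  path <- file.path(dir, "decay.csv")
  write.csv(data.frame(decay_class = 1:5, density = c(0.5, 0.4, 0, 0.2, 0.1)),
            path, row.names = FALSE)
  expect_error(read_decay_density(path), "strictly positive")
  write.csv(data.frame(decay_class = 1:5, density = c(0.5, 0.6, 0.4, 0.3, 0.2)),
            path, row.names = FALSE)
  expect_error(read_decay_density(path), "non-increasing")
  expect_equal(unname(default_decay[["1"]]), 0.54)
})

test_that("litter biomass scales the compressed volume by subsample concentration", {
  expect_equal(litter_plot_biomass(litter_rows()), 0.4)  # 8 L x 50 g/L
  three <- rbind(litter_rows(dry_mass = 25),
                 litter_rows(subplot = "L2", dry_mass = 50),
                 litter_rows(subplot = "L3", dry_mass = 75))
  expect_equal(litter_plot_biomass(three), 0.4)
  expect_equal(litter_plot_biomass(litter_rows(compressed = 0, dry_mass = 0)), 0)
  expect_error(litter_plot_biomass(
    transform(litter_rows(), subsample_volume = 0)), "> 0")
})

test_that("plot_carbon applies area scaling, the 0.474 fraction and 0.03 ha", {
  ds <- one_plot_dataset(litter = litter_rows())
  pools <- plot_carbon(ds, "p1", toy_registry(), default_decay)
  expect_equal(pools$litter, 0.04)            # 0.4 kg x 100 / 1000
  expect_equal(pools$carbon_plot, 0.04 * 0.474)
  expect_equal(pools$total_carbon, 0.632)     # Mg/ha
  expect_equal(pools$live_tree + pools$liana + pools$deadwood + pools$litter,
               pools$biomass_total)

  # small stems scale by 25, large by 1
  ds2 <- one_plot_dataset(stems = rbind(stem_rows(dbh = 10, wsg = 0.5),
                                        stem_rows(dbh = 2, size_class = "small")))
  pools2 <- plot_carbon(ds2, "p1", toy_registry(), default_decay)
  # large: 0.1*(0.5*100) = 5 kg; small: 0.1*(0.5*4) = 0.2 kg x 25 = 5 kg
  expect_equal(pools2$live_tree, 0.010)
  expect_error(plot_carbon(ds2, "nope", toy_registry(), default_decay),
               "not found")
})

test_that("carbon identities hold exactly across a synthetic table", {
  inv <- generate_inventory(small_params(), seed = 21,
                            registry = default_registry,
                            decay_table = default_decay)
  ptab <- plot_carbon_table(inv$dataset, default_registry, default_decay)
  expect_equal(ptab$carbon_plot / ptab$biomass_total,
               rep(0.474, nrow(ptab)))
  expect_equal(ptab$total_carbon * 0.03, ptab$carbon_plot)
  expect_equal(ptab$total_carbon, ptab$live_carbon + ptab$dead_carbon)
  expect_true(all(ptab[c("live_tree", "liana", "deadwood", "litter")] >= 0))
})
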