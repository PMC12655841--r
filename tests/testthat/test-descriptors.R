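test_that("Gibbs energy of fusion follows the constant-Cp form", {
  expect_equal(gibbsFusion(30, 400, 400), 0) # melting-point identity
  expect_equal(gibbsFusion(30, 400, 298.15), 30 * (1 - 298.15 / 400))
  expect_equal(gibbsFusion(30, 400, 298.15), 7.63875, tolerance = 1e-12)
  ## equivalent to dH - T * dS with dS = dH / Tm
  Tm <- 412.3; dH <- 27.9; T <- 310
  expect_equal(gibbsFusion(dH, Tm, T), dH - T * (dH / Tm), tolerance = 1e-12)
  expect_error(gibbsFusion(30, -400, 298), "T_m")
  expect_error(gibbsFusion(30, 400, 0), "'T'")
  expect_error(gibbsFusion(-1, 400, 298), "dH_fus")
})

test_that("mixture weighting is a mole-fraction-weighted sum", {
  one <- mixtureSpec("a", 1)
  expect_equal(mixtureDescriptor(c(a = 7.3), one), 7.3)
  two <- mixtureSpec(c("a", "b"), c(1 / 3, 2 / 3))
  expect_equal(mixtureDescriptor(c(a = 3.0, b = 6.0), two), 5.0)
  ## water as a third solute-free component
  three <- mixtureSpec(c("a", "b", "water"), c(0.4, 0.4, 0.2))
  v <- c(a = 1, b = 2, water = 10)
  expect_equal(mixtureDescriptor(v, three), 0.4 + 0.8 + 2)
  expect_error(mixtureDescriptor(c(a = 1), two), "no descriptor value.*b")
  expect_error(mixtureSpec(c("a", "b"), c(0.5, 0.6)), "sum to 1")
  expect_error(mixtureSpec(c("a", "b"), c(-0.5, 1.5)), "> 0")
})

test_that("mixture weighting is linear in the descriptor values", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    xfrac <- stats::runif(k); xfrac <- xfrac / sum(xfrac)
    mix <- mixtureSpec(letters[1:k], xfrac)
    v <- stats::setNames(stats::rnorm(k), letters[1:k])
    a <- stats::runif(1, -5, 5)
    expect_equal(
      mixtureDescriptor(a * v, mix), a * mixtureDescriptor(v, mix),
      tolerance = 1e-12
    )
  }
})

test_that("relative descriptors are solute minus DES", {
  expect_equal(relativeDescriptor(4.2, 4.2), 0)
  expect_equal(relativeDescriptor(-10.0, -4.0), -6.0)
  expect_error(relativeDescriptor(Inf, 0), "finite")
  expect_identical(deltaName("HBA1"), "ΔHBA1")
})

test_that("assembled feature sets have 16 set1 and 28 set2 columns", {
  raw <- makeRawInputs()
  dt <- assembleFeatureSets(raw$solubility, raw$energetics, raw$curves)
  expect_s4_class(dt, "DescriptorTable")
  expect_identical(length(featureNames(dt, "set1")), 16L)
  expect_identical(length(featureNames(dt, "set2")), 28L)
  expect_true(all(featureNames(dt, "set1") %in% featureNames(dt, "set2")))
  expect_identical(nRecords(dt), nrow(raw$solubility))
  ## spot-check one mixture-weighted value against a hand computation
  x <- featureMatrix(dt)
  expect_equal(
    unname(x[1L, "E_vdW_DES"]),
    0.5 * (-18.0) + 0.5 * (-21.7),
    tolerance = 1e-12
  )
  expect_equal(
    unname(x[1L, "ΔE_vdW"]),
    -35.8 - (0.5 * (-18.0) + 0.5 * (-21.7)),
    tolerance = 1e-12
  )
  expect_equal(unname(x[1L, "log_x_cosmo"]), -2.10)
})

test_that("identical solute and DES descriptors zero every relative column", {
  raw <- makeRawInputs()
  ## make the 'DES' component identical to the solute
  raw$energetics[raw$energetics$species_id == "HBD1g", -1L] <-
    raw$energetics[raw$energetics$species_id == "acidB", -1L]
  raw$curves[[4L]] <- SigmaPotential(
    "HBD1g", sigmaValues(raw$curves[[2L]]), muValues(raw$curves[[2L]])
  )
  dt <- assembleFeatureSets(
    raw$solubility[4L, ], raw$energetics, raw$curves # acidB in pure HBD1g
  )
  x <- featureMatrix(dt)
  delta_cols <- grep("^Δ", colnames(x), value = TRUE)
  expect_length(delta_cols, 17L) # 5 energetic + 12 sigma
  expect_true(all(abs(x[1L, delta_cols]) < 1e-12))
})

test_that("assembly is deterministic and rejects incomplete inputs", {
  raw <- makeRawInputs()
  dt1 <- assembleFeatureSets(raw$solubility, raw$energetics, raw$curves)
  dt2 <- assembleFeatureSets(raw$solubility, raw$energetics, raw$curves)
  expect_identical(featureMatrix(dt1), featureMatrix(dt2))
  expect_error(
    assembleFeatureSets(
      raw$solubility, raw$energetics[-2L, ], raw$curves
    ),
    "record 3 .*acidB.*missing energetics"
  )
  expect_error(
    assembleFeatureSets(raw$solubility, raw$energetics, raw$curves[-5L]),
    "record 2 .*sigma-potential.*water"
  )
  bad <- raw$solubility
  bad$log_x[2L] <- 0.5
  expect_error(assembleFeatureSets(bad, raw$energetics, raw$curves), "<= 0")
})

test_that("CSV readers and feature-table writer round-trip", {
  raw <- makeRawInputs()
  tmp <- withr::local_tempdir()
  utils::write.csv(raw$energetics, file.path(tmp, "species_energetics.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, lapply(raw$curves, function(cv) {
    data.frame(
      species_id = speciesId(cv), sigma = sigmaValues(cv), value = muValues(cv)
    )
  }))
  utils::write.csv(long, file.path(tmp, "sigma_potentials.csv"), row.names = FALSE)
  utils::write.csv(raw$solubility, file.path(tmp, "solubility.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(solute_id = c("acidA", "acidB"), Tm_K = c(400, 380),
               dHfus_kJmol = c(30, 25)),
    file.path(tmp, "fusion.csv"), row.names = FALSE
  )

  en <- readSpeciesEnergetics(file.path(tmp, "species_energetics.csv"))
  cvs <- readSigmaPotentials(file.path(tmp, "sigma_potentials.csv"))
  sol <- readSolubilityTable(file.path(tmp, "solubility.csv"))
  fus <- readFusionData(file.path(tmp, "fusion.csv"))
  expect_equal(fus$dSfus, c(30 / 400, 25 / 380))
  dt <- assembleFeatureSets(sol, en, cvs)
  ref <- assembleFeatureSets(raw$solubility, raw$energetics, raw$curves)
  expect_equal(featureMatrix(dt), featureMatrix(ref), tolerance = 1e-12)

  man <- writeFeatureTables(dt, file.path(tmp, "features"))
  expect_true(file.exists(file.path(tmp, "features", "features_set1.csv")))
  s1 <- utils::read.csv(file.path(tmp, "features", "features_set1.csv"),
                        check.names = FALSE)
  s2 <- utils::read.csv(file.path(tmp, "features", "features_set2.csv"),
                        check.names = FALSE)
  expect_identical(ncol(s1) - 5L, 16L) # 4 record keys + 16 features + log_x
  expect_identical(ncol(s2) - 5L, 28L)
  expect_identical(man$conventions$log_base, 10)
})
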