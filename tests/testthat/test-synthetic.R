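test_that("identical configurations generate bit-identical cohorts", {
  cfg <- synthetic_config(n_samples = 150, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("perfect concordance aligns IHC/FISH labels with true classes", {
  co <- generate_cohort(synthetic_config(n_samples = 300,
                                         ihc_concordance = 1, seed = 4))
  expect_identical(co$ground_truth$ihc_label_class,
                   co$ground_truth$true_her2_class)
  # and the clinical annotation encodes exactly those labels
  got <- as.character(her2_ihc_class(co$clinical))
  expect_identical(got, co$ground_truth$true_her2_class)
})

test_that("realized class counts match planted proportions (binomial check)", {
  p <- c(0.5, 0.25, 0.25)
  n <- 2000
  co <- generate_cohort(synthetic_config(
    n_samples = n, class_proportions = p, seed = 3))
  counts <- table(factor(co$ground_truth$true_her2_class,
                         levels = c("ultralow", "low", "positive")))
  for (i in 1:3) {
    se <- sqrt(n * p[i] * (1 - p[i]))
    expect_lt(abs(counts[[i]] - n * p[i]), 3 * se)
  }
  # per-subgroup planted fractions (class x HR independent), seed 7
  cfg <- synthetic_config(n_samples = 1000, seed = 7)
  co7 <- generate_cohort(cfg)
  planted <- outer(c(`HR-` = 1 - cfg$hr_proportion,
                     `HR+` = cfg$hr_proportion),
                   stats::setNames(cfg$class_proportions,
                                   c("ultralow", "low", "positive")))
  obs <- table(co7$ground_truth$subgroup)
  for (hr in rownames(planted)) for (cl in colnames(planted)) {
    lbl <- paste0(hr, "/HER2",
                  c(ultralow = "-ultralow", low = "-low",
                    positive = "+")[cl])
    pe <- planted[hr, cl]
    se <- sqrt(1000 * pe * (1 - pe))
    expect_lt(abs((if (lbl %in% names(obs)) obs[[lbl]] else 0) - 1000 * pe),
              3 * se)
  }
})

test_that("planted boundaries are the density crossings of adjacent components", {
  cfg <- synthetic_config()
  b <- planted_boundaries(cfg)
  s2 <- log(1 + cfg$her2_component_cv^2)
  sdlog <- sqrt(s2)
  meanlog <- log(cfg$her2_component_means) - s2 / 2
  # numeric oracle: where the two adjacent log-normal densities are equal
  crossing <- function(i) {
    stats::uniroot(function(x)
      stats::dlnorm(x, meanlog[i], sdlog) -
        stats::dlnorm(x, meanlog[i + 1], sdlog),
      interval = cfg$her2_component_means[i:(i + 1)])$root
  }
  expect_equal(b[["ultralow_low"]], crossing(1), tolerance = 1e-6)
  expect_equal(b[["low_positive"]], crossing(2), tolerance = 1e-6)
})

test_that("signature blocks shift only their target subgroup", {
  cfg <- synthetic_config(
    n_samples = 400, seed = 12,
    signatures = list(list(name = "blk", n_genes = 5,
                           target_subgroup = "HR+/HER2-ultralow",
                           shift_sd = 4)))
  co <- generate_cohort(cfg)
  g <- co$expression["blk_g01", ]
  target <- co$ground_truth$subgroup == "HR+/HER2-ultralow"
  expect_gt(mean(g[target]), mean(g[!target]) * 1.5)
  sets <- generate_signature_set(cfg)
  expect_identical(sets$blk, sprintf("blk_g%02d", 1:5))
  expect_true(all(sets$blk %in% rownames(co$expression)))
})

test_that("adding a signature block never perturbs earlier blocks", {
  base <- synthetic_config(n_samples = 120, seed = 5)
  extra <- synthetic_config(
    n_samples = 120, seed = 5,
    signatures = c(base$signatures,
                   list(list(name = "zzz_new", n_genes = 7,
                             target_subgroup = "HR+/HER2+",
                             shift_sd = 2))))
  co1 <- generate_cohort(base)
  co2 <- generate_cohort(extra)
  expect_identical(co1$expression["216836_s_at", ],
                   co2$expression["216836_s_at", ])
  expect_identical(co1$expression["205225_at", ], co2$expression["205225_at", ])
  bg <- grep("^bg_", rownames(co1$expression), value = TRUE)
  expect_identical(co1$expression[bg, ], co2$expression[bg, ])
  expect_identical(co1$clinical, co2$clinical)
})

test_that("censoring rate calibration holds and survival follows the hazards", {
  cfg <- synthetic_config(n_samples = 2000, seed = 21, censoring_rate = 0.3)
  co <- generate_cohort(cfg)
  frac_cens <- mean(co$clinical$event_rfs == 0)
  expect_lt(abs(frac_cens - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  # uncensored configuration has events everywhere
  co0 <- generate_cohort(synthetic_config(n_samples = 100, seed = 21,
                                          censoring_rate = 0))
  expect_true(all(co0$clinical$event_os == 1))
})

test_that("invalid configurations are rejected with the violation listed", {
  expect_error(synthetic_config(her2_component_means = c(3, 2, 1)),
               "increasing")
  expect_error(synthetic_config(class_proportions = c(0.5, 0.2, 0.2)),
               "summing to 1")
  expect_error(synthetic_config(ihc_concordance = 0.4), "concordance")
  expect_error(synthetic_config(esr1_means = c(600, 1200)), "straddling")
  expect_error(synthetic_config(hazard_ratios = c("HR+/HER2+" = 1)),
               "hazard_ratios")
  expect_error(
    synthetic_config(signatures = list(list(name = "x", n_genes = 0,
                                            target_subgroup = "HR+/HER2+",
                                            shift_sd = 1))),
    "signature")
  expect_error(generate_signature_set(synthetic_config(signatures = list())),
               "no signatures")
})

test_that("cohorts and signature sets round-trip through the writers", {
  cfg <- synthetic_config(n_samples = 40, n_background_genes = 10, seed = 8)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_identical(read_expression_matrix(file.path(dir, "expression.tsv")),
                   co$expression)
  cl <- read_clinical_table(file.path(dir, "clinical.tsv"))
  expect_equal(cl$time_rfs, co$clinical$time_rfs)
  expect_identical(cl$fish_status, co$clinical$fish_status)
  expect_identical(read_gmt(file.path(dir, "signatures.gmt")),
                   generate_signature_set(cfg))
  # byte-identical rewrite
  dir2 <- withr::local_tempdir()
  write_cohort(co, dir2)
  for (f in c("expression.tsv", "clinical.tsv", "signatures.gmt",
              "ground_truth.json"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
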