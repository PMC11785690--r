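# Deterministic data-assembly rules: biopsy selection, the one-year window,
# fibrosis collapsing, derived ratios, idempotence and the raw-record round
# trip.

toyBiopsies <- function() data.frame(
  subject_id = c("s1", "s1", "s2", "s3", "s3", "s4"),
  biopsy_date = as.Date(c("2005-01-01", "2006-02-05",   # s1: two biopsies
                          "2005-06-01",                  # s2: single
                          "2005-03-02", "2005-05-01",    # s3: equidistant tie (30 days each)
                          "2005-09-01")),                # s4: no liver panel
  steatosis = c(1, 2, 3, 0, 1, 2),
  lobular_inflammation = c(1, 1, 2, 1, 2, 3),
  ballooning = c(0, 1, 2, 0, 1, 1),
  portal_inflammation = c(0, 1, 1, 0, 0, 2),
  fibrosis = c("1b", "2", "1a", "0", "1c", "4"),
  microvesicular_steatosis = 0, microgranulomas = 0,
  large_lipogranulomas = 0, acidophil_bodies = 1,
  pigmented_macrophages = 0, megamitochondria = 0,
  mallory_hyaline = 1, glycogen_nuclei = 0,
  lesion_location = "zone3",
  stringsAsFactors = FALSE)

toyPanel <- function() data.frame(
  subject_id = c("s1", "s2", "s3"),
  panel_date = as.Date(c("2006-01-16",   # day 380 after s1 biopsy 1
                         "2005-06-10",
                         "2005-04-01")), # equidistant from both s3 biopsies
  alt = c(80, 55, 40), ast = c(40, 44, 44),
  stringsAsFactors = FALSE)

test_that("biopsy selection follows the smallest-distance rule with earlier tie-break", {
  sel <- selectBiopsy(toyBiopsies(), toyPanel())
  expect_identical(nrow(sel), 4L)
  # s1: biopsies at day 0 and ~400, panel at day 380 -> the later biopsy
  expect_identical(sel$biopsy_date[sel$subject_id == "s1"], as.Date("2006-02-05"))
  # s2: single biopsy -> itself
  expect_identical(sel$biopsy_date[sel$subject_id == "s2"], as.Date("2005-06-01"))
  # s3: equidistant (31 days each) -> earlier biopsy
  expect_identical(sel$biopsy_date[sel$subject_id == "s3"], as.Date("2005-03-02"))
  # s4: no panel -> earliest biopsy, logged as fallback
  expect_identical(attr(sel, "fallback"), "s4")
  # permutation invariance of the tie-break
  perm <- toyBiopsies()[c(5, 1, 6, 3, 4, 2), ]
  sel2 <- selectBiopsy(perm, toyPanel())
  expect_identical(sel2$biopsy_date, sel$biopsy_date)
})

test_that("subjects without a biopsy are absent from the output", {
  lp <- rbind(toyPanel(), data.frame(subject_id = "ghost",
                                     panel_date = as.Date("2005-01-01"),
                                     alt = 50, ast = 30))
  out <- preprocessRecords(toyBiopsies(), lp,
                           data.frame(subject_id = character(), date = as.Date(character()),
                                      name = character(), value = character()))
  expect_identical(rownames(out$responses), c("s1", "s2", "s3", "s4"))
})

test_that("biomarkers attach by nearest date within 365 days, earlier on ties", {
  chosen <- data.frame(subject_id = "s1", biopsy_date = as.Date("2005-06-01"))
  bm <- data.frame(
    subject_id = "s1",
    date = as.Date(c("2005-05-02", "2005-06-11",     # -30 and +10 days
                     "2006-06-06",                    # 370 days: outside
                     "2005-05-22", "2005-06-11")),    # equidistant +-10
    name = c("hba1c", "hba1c", "ferritin", "tsh", "tsh"),
    value = c("5.0", "6.0", "140", "1.1", "2.2"),
    stringsAsFactors = FALSE)
  out <- attachBiomarkers(chosen, bm)
  expect_identical(out$hba1c, "6.0")        # nearest (+10 beats -30)
  expect_true(is.na(out$ferritin))          # 370 days -> missing
  expect_identical(out$tsh, "1.1")          # equidistant -> earlier record
  # boundary: exactly 365 days still attaches, 366 does not
  b365 <- data.frame(subject_id = "s1", date = as.Date("2005-06-01") + 365,
                     name = "x", value = "1")
  b366 <- data.frame(subject_id = "s1", date = as.Date("2005-06-01") + 366,
                     name = "y", value = "1")
  expect_identical(attachBiomarkers(chosen, b365)$x, "1")
  expect_true(is.na(attachBiomarkers(chosen, b366)$y))
})

test_that("fibrosis collapsing is order-preserving and surjective onto 0..4", {
  raw <- c("0", "1a", "1b", "1c", "1", "2", "3", "4")
  expect_identical(collapseFibrosis(raw), c(0L, 1L, 1L, 1L, 1L, 2L, 3L, 4L))
  expect_setequal(unique(collapseFibrosis(raw)), 0:4)
  expect_true(all(diff(collapseFibrosis(c("0", "1a", "2", "3", "4"))) > 0))
  expect_identical(collapseFibrosis(c("2", NA)), c(2L, NA))
  expect_error(collapseFibrosis("5b"), "unknown fibrosis code")
})

test_that("derived ratios compute by division and propagate missingness", {
  row <- data.frame(ast = 40, alt = 80, waist_circumference = 108,
                    hip_circumference = 115)
  out <- deriveCovariates(row)
  expect_equal(out$ast_alt, 0.5, tolerance = 1e-12)
  expect_equal(out$waist_hip, 108 / 115, tolerance = 1e-12)
  row2 <- data.frame(ast = 40, alt = NA_real_, waist_circumference = NA_real_,
                     hip_circumference = 115)
  out2 <- deriveCovariates(row2)
  expect_true(is.na(out2$ast_alt))
  expect_true(is.na(out2$waist_hip))
})

test_that("full preprocessing is deterministic, idempotent and drops lesion location", {
  bm <- data.frame(subject_id = c("s1", "s2"),
                   date = as.Date(c("2006-02-10", "2005-06-20")),
                   name = "hba1c", value = c("6.1", "5.5"),
                   stringsAsFactors = FALSE)
  o1 <- preprocessRecords(toyBiopsies(), toyPanel(), bm)
  o2 <- preprocessRecords(toyBiopsies(), toyPanel(), bm)
  expect_identical(o1, o2)
  expect_false("lesion_location" %in% colnames(o1$responses))
  expect_false("lesion_location" %in% names(o1$covariates))
  # item extraction with collapsed fibrosis
  expect_identical(unname(o1$responses["s1", "fibrosis"]), 2L)
  expect_identical(unname(o1$responses["s3", "fibrosis"]), 0L)
  # liver-panel values ride the same window rule; ratio derived
  expect_equal(o1$covariates["s1", "ast_alt"], 40 / 80, tolerance = 1e-12)
  # no covariate violates the 365-day rule (re-scan)
  expect_true(is.na(o1$covariates["s4", "hba1c"]))
})

test_that("raw synthetic records round-trip through preprocessing", {
  cfg <- defaultTruth(250L)
  raw <- generateRawRecords(cfg, seed = 71)
  out <- preprocessRecords(raw$biopsies, raw$liver_panel, raw$biomarkers)
  pop <- raw$population
  ids <- rownames(pop$responses)
  expect_setequal(rownames(out$responses), ids)
  resp <- out$responses[ids, colnames(pop$responses)]
  expect_identical(unname(resp), unname(pop$responses))
  # biopsy-count mixture matches the configured default
  counts <- table(table(raw$biopsies$subject_id))
  expect_gt(counts[["1"]] / 250, 0.75)
  # covariates round-trip (derived ratios recomputed; the deliberate
  # out-of-window boundary fixture for subject 1's tsh is excluded)
  tab <- cfg@covariates
  for (nm in tab$name[!tab$derived & tab$kind == "continuous"]) {
    a <- suppressWarnings(as.numeric(out$covariates[ids, nm]))
    b <- pop$covariates[[nm]]
    keep <- seq_along(ids)
    if (nm == "tsh") keep <- keep[ids[keep] != "1"]
    expect_equal(a[keep], b[keep], tolerance = 1e-9)
  }
  # the boundary fixture ends missing
  expect_true(is.na(out$covariates["1", "tsh"]))
})
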