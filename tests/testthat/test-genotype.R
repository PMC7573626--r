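test_that("allelic ratio transform matches the high-ITD threshold and is monotone", {
  expect_equal(vaf_to_allelic_ratio(1/3), 0.5)
  expect_identical(vaf_to_allelic_ratio(0.5), 1)
  expect_identical(vaf_to_allelic_ratio(0), 0)
  expect_error(vaf_to_allelic_ratio(1), "0 <= vaf < 1")
  grid <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(vaf_to_allelic_ratio(grid)) > 0))
})

test_that("FLT3-ITD burden is called on the maximum ITD VAF", {
  expect_equal(classify_flt3_itd(muts(list("FLT3", "ITD", 0.40))), "high")
  expect_equal(classify_flt3_itd(muts(list("FLT3", "ITD", 0.33))), "high")
  expect_equal(classify_flt3_itd(muts(list("FLT3", "ITD", 0.10))), "low")
  expect_equal(classify_flt3_itd(muts(list("FLT3", "TKD-D835", 0.45))), "absent")
  expect_equal(classify_flt3_itd(empty_mutations()), "absent")
  # multiple ITD calls: max decides; level is non-decreasing in max VAF
  two <- muts(list("FLT3", "ITD", 0.10), list("FLT3", "ITD", 0.35))
  expect_equal(classify_flt3_itd(two), "high")
  levels_seen <- vapply(seq(0, 0.9, by = 0.05), function(v) {
    classify_flt3_itd(muts(list("FLT3", "ITD", v)))
  }, character(1))
  rank <- c(low = 1, high = 2)[levels_seen]
  expect_true(all(diff(rank) >= 0))
})

test_that("the eight NPM1 x FLT3-ITD x DNMT3A combinations map to the documented categories", {
  # hand-enumerated truth table
  cases <- list(
    list(npm1 = FALSE, itd = FALSE, dnmt3a = FALSE, category = 2L),
    list(npm1 = TRUE,  itd = FALSE, dnmt3a = FALSE, category = 1L),
    list(npm1 = FALSE, itd = TRUE,  dnmt3a = FALSE, category = 4L),
    list(npm1 = TRUE,  itd = TRUE,  dnmt3a = FALSE, category = 3L),
    list(npm1 = FALSE, itd = FALSE, dnmt3a = TRUE,  category = 5L),
    list(npm1 = TRUE,  itd = FALSE, dnmt3a = TRUE,  category = 5L),
    list(npm1 = FALSE, itd = TRUE,  dnmt3a = TRUE,  category = 5L),
    list(npm1 = TRUE,  itd = TRUE,  dnmt3a = TRUE,  category = 5L)
  )
  for (cs in cases) {
    m <- list()
    if (cs$npm1) m <- c(m, list(list("NPM1", "typeA", 0.44)))
    if (cs$itd) m <- c(m, list(list("FLT3", "ITD", 0.20)))
    if (cs$dnmt3a) m <- c(m, list(list("DNMT3A", "R882", 0.47)))
    expect_equal(classify_category(do.call(muts, m)), cs$category)
  }
})

test_that("category ignores other genes and ITD burden level; flags mark IDH1-R132H", {
  # other mutations never change the category
  expect_equal(classify_category(muts(list("IDH1", "R132H", 0.42))), 2L)
  expect_equal(classify_category(
    muts(list("NPM1", "typeA", 0.45), list("TET2", "mut", 0.4))), 1L)
  # ITD presence, not level, decides categories 3/4
  expect_equal(classify_category(
    muts(list("NPM1", "typeA", 0.44), list("FLT3", "ITD", 0.05))), 3L)
  # the DNMT3A override example
  expect_equal(classify_category(
    muts(list("NPM1", "typeA", 0.44), list("FLT3", "ITD", 0.20),
         list("DNMT3A", "R882", 0.47))), 5L)

  cl <- rbind(clinical_row("P1"), clinical_row("P2"))
  mu <- rbind(mutation_rows("P1", "IDH1", "R132H", 0.42),
              mutation_rows("P2", "IDH1", "R132C", 0.40))
  cls <- classify_cohort(new_cohort(cl, mu))
  expect_equal(cls$category, c(2L, 2L))
  expect_equal(cls$flags, c("idh1_r132h", ""))
})

test_that("gene-only ELN 2017 risk follows the hand-enumerated case list", {
  eln <- function(...) classify_eln2017(muts(...))
  expect_equal(eln(list("NPM1", "typeA", 0.44)), "favorable")
  expect_equal(eln(list("NPM1", "typeA", 0.44), list("FLT3", "ITD", 0.10)),
               "favorable")
  expect_equal(eln(list("NPM1", "typeA", 0.44), list("FLT3", "ITD", 0.40)),
               "intermediate")
  expect_equal(eln(list("FLT3", "ITD", 0.40)), "adverse")
  expect_equal(eln(list("FLT3", "ITD", 0.10)), "intermediate")
  expect_equal(classify_eln2017(empty_mutations()), "intermediate")
  expect_equal(eln(list("CEBPA", "biallelic", 0.45)), "favorable")
  expect_equal(eln(list("RUNX1", "mut", 0.40)), "adverse")
  expect_equal(eln(list("TP53", "mut", 0.40)), "adverse")
  # TP53 never yields to a favorable lesion
  expect_equal(eln(list("NPM1", "typeA", 0.44), list("TP53", "mut", 0.3)),
               "adverse")
})

test_that("the RUNX1/ASXL1 co-occurrence caveat is configurable", {
  m <- muts(list("NPM1", "typeA", 0.44), list("RUNX1", "mut", 0.30))
  expect_equal(classify_eln2017(m), "favorable")
  strict <- eln_rules(runx1_asxl1_yield = FALSE)
  expect_equal(classify_eln2017(m, rules = strict), "adverse")
  m2 <- muts(list("CEBPA", "DM", 0.45), list("ASXL1", "mut", 0.2))
  expect_equal(classify_eln2017(m2), "favorable")
  expect_equal(classify_eln2017(m2, rules = strict), "adverse")
})

test_that("DNMT3A modification moves exactly the DNMT3A-mutated patients to adverse", {
  expect_equal(classify_eln_dnmt3a(muts(list("NPM1", "typeA", 0.4),
                                        list("DNMT3A", "R882", 0.45)),
                                   "favorable"), "adverse")
  expect_equal(classify_eln_dnmt3a(muts(list("DNMT3A", "non-R882", 0.4)),
                                   "intermediate"), "adverse")
  expect_equal(classify_eln_dnmt3a(muts(list("RUNX1", "mut", 0.4)),
                                   "adverse"), "adverse")

  co <- generate_cohort(quick_config(400, seed = 7, keep_cooccurrence = TRUE))
  cls <- classify_cohort(co)
  has_dnmt3a <- cls$patient_id %in%
    co$mutations$patient_id[co$mutations$gene == "DNMT3A"]
  differs <- cls$eln2017 != cls$eln_dnmt3a
  expect_true(all(differs == (has_dnmt3a & cls$eln2017 != "adverse")))
  expect_true(all(cls$eln_dnmt3a[has_dnmt3a] == "adverse"))
})

test_that("classification is total and deterministic on random mutation lists", {
  set.seed(11)
  genes <- c("NPM1", "FLT3", "DNMT3A", "IDH1", "IDH2", "RUNX1", "ASXL1",
             "TP53", "CEBPA", "TET2")
  subs <- c("typeA", "ITD", "TKD-D835", "R882", "R132H", "mut", "biallelic")
  for (i in 1:50) {
    k <- sample(0:5, 1)
    m <- if (k == 0) empty_mutations() else
      mutation_rows("P1", sample(genes, k, replace = TRUE),
                    sample(subs, k, replace = TRUE), runif(k, 0, 0.6))
    cat1 <- classify_category(m)
    expect_true(cat1 %in% 1:5)
    lvl <- classify_flt3_itd(m)
    expect_true(lvl %in% c("absent", "low", "high"))
    risk <- classify_eln2017(m, lvl)
    expect_true(risk %in% c("favorable", "intermediate", "adverse"))
    expect_identical(classify_category(m), cat1)
    expect_true((lvl == "absent") ==
                  !any(m$gene == "FLT3" & grepl("ITD", m$subtype)))
  }
})
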