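# Evidence integration: mode calls, scoring, evidence tables, reports.

test_that("mode calls follow the knockout sign convention", {
  expect_equal(classify_mode(5.5), "repressor")   # ybdN in the citR KO
  expect_equal(classify_mode(-1.4), "activator")  # dhaK in the dhfA KO
  expect_equal(classify_mode(0), "unknown")
  expect_equal(classify_mode(c(-2.81, 0.5, 2)),
               c("activator", "unknown", "repressor"))
})

test_that("negating all fold changes swaps activator and repressor exactly", {
  withr::with_seed(41L, {
    lfc <- runif(200L, -6, 6)
    m1 <- classify_mode(lfc)
    m2 <- classify_mode(-lfc)
    expect_equal(m1 == "activator", m2 == "repressor")
    expect_equal(m1 == "unknown", m2 == "unknown")
  })
})

test_that("the additive score counts evidence streams and is monotone", {
  full <- data.frame(has_chip_peak = TRUE, has_predicted_site = TRUE,
                     deg_log2fc = -2, deg_p = 0.001,
                     conserved_neighbor = TRUE)
  expect_equal(score_target(full), 4)
  deg_only <- data.frame(has_chip_peak = FALSE, has_predicted_site = FALSE,
                         deg_log2fc = 3, deg_p = 0.01,
                         conserved_neighbor = FALSE)
  expect_equal(score_target(deg_only), 1)
  withr::with_seed(42L, {
    for (trial in 1:20) {
      row <- data.frame(has_chip_peak = sample(c(TRUE, FALSE), 1L),
                        has_predicted_site = sample(c(TRUE, FALSE), 1L),
                        deg_log2fc = runif(1, -4, 4),
                        deg_p = runif(1),
                        conserved_neighbor = sample(c(TRUE, FALSE), 1L))
      base <- score_target(row)
      for (flag in c("has_chip_peak", "has_predicted_site",
                     "conserved_neighbor")) {
        up <- row; up[[flag]] <- TRUE
        expect_gte(score_target(up), base)
      }
    }
  })
})

test_that("no evidence means an empty table and a zero-target report", {
  empty_degs <- data.frame(locus_tag = character(0L), gene = character(0L),
                           base_mean = numeric(0L), log2fc = numeric(0L),
                           pvalue = numeric(0L))
  ev <- build_evidence_table("tfX", empty_degs)
  expect_equal(nrow(ev), 0L)
  rep <- regulon_report("tfX", ev)
  expect_equal(rep$n_degs, 0L)
  expect_false(rep$autoregulation)
  expect_no_error(regulon_json(rep))
})

test_that("the ptrR/sad worked example yields a direct repressor call and autoregulation", {
  g <- toy_genome()
  degs <- deg_table(5L)  # sad +1.32 (p 0.022), yneJ -6.69, yneK +2.78
  peaks <- data.frame(contig = "chr", start = 1975L, end = 2025L)
  ap <- assign_peak_targets(peaks, g)
  ev <- build_evidence_table("b1526", degs, ap,
                             operons = group_operons(g))
  sad <- ev[ev$target == "b1525", ]
  expect_equal(sad$mode, "repressor")
  expect_true(sad$direct)
  expect_true(sad$has_chip_peak)
  # the TF's own deletion artifact (-6.69) is excluded from targets
  expect_false("b1526" %in% ev$target)
  rep <- regulon_report("b1526", ev, ap)
  expect_true(rep$autoregulation)
})

test_that("a peak upstream of the waa operon head calls the operon an activator", {
  g <- toy_genome()
  degs <- deg_table(3L)
  degs$locus_tag <- degs$gene  # key the toy genome by gene name
  degs$locus_tag[degs$gene == "waaZ"] <- "waa1"
  degs$locus_tag[degs$gene == "waaY"] <- "waa2"
  degs$locus_tag[degs$gene == "waaL"] <- "waa3"
  degs$locus_tag[degs$gene == "waaU"] <- "waa4"
  degs$locus_tag[degs$gene == "waaS"] <- "waa5"
  degs$locus_tag[degs$gene == "waaG"] <- "waa6"
  degs$locus_tag[degs$gene == "waaP"] <- "waa7"
  degs$locus_tag[degs$gene == "waaO"] <- "waa8"
  peaks <- data.frame(contig = "chr", start = 3440L, end = 3490L)
  ap <- assign_peak_targets(peaks, g)
  ev <- build_evidence_table("lpsR", degs, ap,
                             operons = group_operons(g))
  op <- ev[ev$target == "operon_waa1", ]
  expect_equal(nrow(op), 1L)
  expect_equal(op$mode, "activator")
  expect_true(op$direct)
  # representative effect is the strongest member (waaL -2.81)
  expect_equal(op$deg_log2fc, -2.81)
})

test_that("conservation plus expression without binding yields an indirect target", {
  # citR-style: binding at own promoter only; the citrate-lyase cluster is
  # conserved and upregulated but has no detected peak
  degs <- data.frame(locus_tag = c("citC", "citE", "citF"),
                     gene = c("citC", "citE", "citF"),
                     base_mean = c(12, 9, 20),
                     log2fc = c(4.0, 4.4, 3.3),
                     pvalue = c(3.64e-07, 7.69e-07, 3.40e-08))
  ev <- build_evidence_table("citR", degs, annotated_peaks = NULL,
                             conserved = c("citC", "citE", "citF"))
  expect_true(all(!ev$direct))
  expect_true(all(ev$mode == "repressor"))
  expect_true(all(ev$conserved_neighbor))
  expect_true(all(ev$score == 2))
})

test_that("report JSON is byte-stable and carries the summary counts", {
  g <- toy_genome()
  degs <- deg_table(5L)
  ap <- assign_peak_targets(data.frame(contig = "chr", start = 1975L,
                                       end = 2025L), g)
  ev <- build_evidence_table("b1526", degs, ap)
  r1 <- regulon_json(regulon_report("b1526", ev, ap))
  r2 <- regulon_json(regulon_report("b1526", ev, ap))
  expect_identical(r1, r2)
  parsed <- jsonlite::fromJSON(r1, simplifyVector = FALSE)
  expect_equal(parsed$tf, "b1526")
  expect_equal(parsed$n_binding_sites$chip, 1L)
})

test_that("auprc handles perfect, inverted and tied rankings", {
  expect_equal(auprc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_lt(auprc(c(1, 2, 3), c(TRUE, FALSE, FALSE)), 0.5)
  expect_equal(auprc(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  expect_true(is.na(auprc(1:3, rep(FALSE, 3L))))
})
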