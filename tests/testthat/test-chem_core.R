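test_that("meq conversion matches hand arithmetic and is linear", {
    # 230 mg/L Na / 22.99 g/mol, z = 1
    expect_close(toMeq(230, "Na"), 230 / 22.99)
    expect_close(toMeq(230, "Na"), 10.00435, tol = 1e-4)
    # one molar mass of a divalent ion -> 2 meq/L
    expect_close(toMeq(40.08, "Ca"), 2)
    expect_close(toMeq(0, "SO4"), 0)
    # linearity in concentration
    a <- runif(5, 0, 100); b <- runif(5, 0, 100)
    for (ion in c("Na", "Ca", "PO4"))
        expect_close(toMeq(a + b, ion), toMeq(a, ion) + toMeq(b, ion))
    expect_error(toMeq(1, "Xx"), "unknown ion")
    expect_error(toMeq(-1, "Na"), ">= 0")
})

test_that("charge balance error is signed, bounded and antisymmetric", {
    # symmetric: 10 meq/L of Na against 10 meq/L of Cl
    bal <- icbe(c(Na = 10 * 22.99, Cl = 10 * 35.453))
    expect_close(bal$icbe, 0)
    expect_true(bal$acceptable)
    # cations 5 meq, anions 4 meq -> +100/9 %
    b2 <- icbe(c(Na = 5 * 22.99, Cl = 4 * 35.453))
    expect_close(b2$icbe, 100 / 9, tol = 1e-6)
    expect_false(b2$acceptable)
    # antisymmetry under swapping the cation and anion totals
    b3 <- icbe(c(Na = 4 * 22.99, Cl = 5 * 35.453))
    expect_close(b3$icbe, -b2$icbe)
    expect_error(icbe(c(Na = 1)), "cation and one anion")
})

test_that("missing concentrations are excluded from sums with a warning", {
    v <- c(Na = 10 * 22.99, K = NA, Cl = 10 * 35.453)
    expect_warning(b <- icbe(v), "excluded")
    expect_close(b$icbe, 0)
})

test_that("group summaries use the n-1 sd and respect ordering", {
    conc <- cbind(A = c(Cr = 1.0), B = c(Cr = 3.0))
    wcs <- WaterChemSet(conc, data.frame(group = c("mining", "mining"),
                                         row.names = c("A", "B")))
    gs <- groupSummary(wcs)
    expect_close(gs$mean, 2)
    expect_close(gs$sd, sd(c(1, 3)))
    expect_close(gs$sd, 1.414214, tol = 1e-5)
    # single observation: degenerate sd reported as 0 and flagged
    one <- WaterChemSet(cbind(A = c(Cr = 1.0)),
                        data.frame(group = "mining", row.names = "A"))
    g1 <- groupSummary(one)
    expect_identical(g1$sd, 0)
    expect_true(g1$degenerate)
    # min <= mean <= max for every parameter on a larger survey
    gs2 <- groupSummary(smallSurvey())
    expect_true(all(gs2$min <= gs2$mean + 1e-12))
    expect_true(all(gs2$mean <= gs2$max + 1e-12))
})

test_that("the container validates group labels, pH and nonnegativity", {
    expect_error(WaterChemSet(cbind(A = c(Cr = 1)),
                              data.frame(group = "urban", row.names = "A")),
                 "group")
    expect_error(WaterChemSet(cbind(A = c(Cr = -1)),
                              data.frame(group = "mining", row.names = "A")),
                 "negative")
    expect_error(WaterChemSet(cbind(A = c(pH = 15)),
                              data.frame(group = "mining", row.names = "A")),
                 "pH")
    # ORP may legitimately be negative
    wcs <- WaterChemSet(cbind(A = c(ORP = -50, Cr = 1)),
                        data.frame(group = "mining", row.names = "A"))
    expect_s4_class(wcs, "WaterChemSet")
})

test_that("the CSV round trip preserves the survey", {
    wcs <- smallSurvey()
    f <- tempfile(fileext = ".csv")
    writeWaterSamples(wcs, f)
    back <- readWaterSamples(f)
    expect_equal(dim(back), dim(wcs))
    expect_equal(concMatrix(back), concMatrix(wcs))
    expect_equal(as.character(sampleGroup(back)),
                 as.character(sampleGroup(wcs)))
    expect_error(readWaterSamples(textConnectionPath <- {
        f2 <- tempfile(fileext = ".csv")
        writeLines("sample_id,group\nA,mining\nA,mining", f2)
        f2
    }), "duplicated")
})
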