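test_that("chronic daily intake reproduces the published worked examples", {
    # 4.5 mg/L Cr: child (2 L / 18 kg), male (2.5 L / 65 kg),
    # female (3 L / 62 kg) under the lifetime convention
    expect_close(cdi(4.5, "child"), 0.5)
    expect_equal(round(cdi(4.5, "male"), 3), 0.173)
    expect_equal(round(cdi(4.5, "female"), 3), 0.218)
    expect_close(cdi(0, "child"), 0)
    # the printed-constant convention is ~ED*EF/AT = 4.79x larger
    pp <- exposureProfiles("printed")
    expect_close(cdi(4.5, "child", pp) / cdi(4.5, "child"),
                 350 * 365 / (70 * 365))
    expect_error(cdi(4.5, "adult"), "unknown cohort")
    expect_error(cdi(-1, "child"), ">= 0")
})

test_that("hazard quotient, index and cancer risk follow the risk chain", {
    expect_close(hazardQuotient(0.5, "Cr"), 0.5 / 1.5)
    expect_equal(round(hazardQuotient(0.5, "Cr"), 3), 0.333)
    expect_close(hazardQuotient(0.25, "Ni"), 12.5)
    expect_close(hazardQuotient(0, "Mn"), 0)
    expect_error(hazardQuotient(1, "Fe"), "no RfD")
    expect_close(hazardIndex(c(0.333, 12.5, 0.8)), 13.633)
    expect_close(hazardIndex(0.7), 0.7)  # single metal: identity
    expect_close(hazardIndex(c(0, 0, 0)), 0)
    expect_close(cancerRisk(0.5, "Cr"), 0.25)
    expect_equal(round(cancerRisk(0.244, "Ni"), 3), 0.222)
    expect_close(cancerRisk(0, "Cr"), 0)
    expect_error(cancerRisk(1, "Mn"), "not carcinogenic")
})

test_that("total hazard index sums published endpoint values", {
    # chromite-mine-water children, carcinogenic endpoints
    expect_close(totalHazardIndex(c(0.333, 0.228), "carcinogenic"), 0.561)
    expect_close(totalHazardIndex(c(0.319, 0.223), "carcinogenic"), 0.542)
    expect_close(totalHazardIndex(0.4), 0.4)
    expect_error(totalHazardIndex(numeric(0)), "empty")
})

test_that("every risk quantity is degree-1 homogeneous in concentration", {
    set.seed(3)
    for (i in 1:10) {
        conc <- runif(1, 0, 5); s <- runif(1, 0.1, 10)
        for (co in c("child", "male", "female")) {
            expect_close(cdi(conc * s, co), s * cdi(conc, co))
            expect_close(hazardQuotient(cdi(conc * s, co), "Ni"),
                         s * hazardQuotient(cdi(conc, co), "Ni"))
            expect_close(cancerRisk(cdi(conc * s, co), "Cr"),
                         s * cancerRisk(cdi(conc, co), "Cr"))
        }
    }
})

test_that("cohort ordering child > female > male holds at fixed concentration", {
    prof <- exposureProfiles()
    ir_bw <- prof$IR / prof$BW
    names(ir_bw) <- prof$cohort
    expect_true(ir_bw["child"] > ir_bw["female"])
    expect_true(ir_bw["female"] > ir_bw["male"])
    for (conc in c(0.1, 1, 4.5))
        expect_true(cdi(conc, "child") > cdi(conc, "female") &&
                    cdi(conc, "female") > cdi(conc, "male"))
})

test_that("the survey-level chain is consistent between views", {
    wcs <- smallSurvey()
    hr <- healthRisk(wcs)
    expect_true(all(hr$perSample$cdi >= 0))
    expect_true(all(is.na(hr$perSample$cr[hr$perSample$metal == "Mn"])))
    # HI >= each contributing HQ
    for (i in seq_len(nrow(hr$hi))) {
        sub <- hr$perSample[hr$perSample$sample_id == hr$hi$sample_id[i] &
                            hr$perSample$cohort == hr$hi$cohort[i], ]
        expect_close(hr$hi$hi[i], sum(sub$hq))
        expect_true(all(hr$hi$hi[i] >= sub$hq - 1e-12))
    }
    rs <- riskSummary(wcs)
    # THI rows are column sums of the per-metal endpoint statistics
    for (i in seq_len(nrow(rs$thi))) {
        sub <- rs$perMetal[rs$perMetal$group == rs$thi$group[i] &
                           rs$perMetal$cohort == rs$thi$cohort[i] &
                           !is.na(rs$perMetal$cr_min), ]
        expect_close(rs$thi$min[i], sum(sub$cr_min))
        expect_close(rs$thi$max[i], sum(sub$cr_max))
    }
})
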