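# Small in-code fixtures shared across test files.

# Two-well fixture with hand-checkable chemistry.
smallSurvey <- function() {
    conc <- cbind(
        W1 = c(pH = 7.5, EC = 1500, TDS = 1000, Turbidity = 3,
               Na = 230, K = 3.9098, Ca = 40.08, Mg = 24.305,
               HCO3 = 305.085, Cl = 177.265, SO4 = 96.06, NO3 = 62.004,
               PO4 = 9.4971, Cr = 1.0, Ni = 1.0, Mn = 0.1),
        W2 = c(pH = 7.0, EC = 300, TDS = 500, Turbidity = 6,
               Na = 46, K = 7.8196, Ca = 80.16, Mg = 12.15,
               HCO3 = 152.5, Cl = 88.6, SO4 = 192.1, NO3 = 31.0,
               PO4 = 4.75, Cr = 3.0, Ni = 0.5, Mn = 0.6))
    WaterChemSet(conc, data.frame(group = c("mining", "non_mining"),
                                  x = c(0, 1), y = c(0, 1),
                                  row.names = colnames(conc)))
}

expect_close <- function(actual, expected, tol = 1e-6) {
    expect_equal(unname(actual), unname(expected), tolerance = tol,
                 ignore_attr = TRUE)
}
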