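# At-threshold / one step inside / one step outside for every printed
# inequality of the rule. `eps` is an ULP-scale step for continuous
# measures and one reporting unit for counts.
boundary_cases <- function() {
  eps <- 1e-9
  rbind(
    data.frame(kind = "TEMPERATURE", value = c(36, 36 - eps, 36 + 1e-6,
                                               38, 38 + eps, 38 - 1e-6),
               hit = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
               id = "SIRS_TEMP"),
    data.frame(kind = "RESPIRATORY_RATE", value = c(20, 20 + eps, 20 - 1e-6),
               hit = c(TRUE, TRUE, FALSE), id = "SIRS_RR"),
    data.frame(kind = "HEART_RATE", value = c(90, 90 + eps, 90 - 1e-6, 89),
               hit = c(TRUE, TRUE, FALSE, FALSE), id = "SIRS_HR"),
    data.frame(kind = "WBC_COUNT", value = c(4000, 4000 - 1, 4001,
                                             12000, 12001, 11999),
               hit = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), id = "SIRS_WBC"),
    data.frame(kind = "BANDS_PERCENT", value = c(10, 10 + 1e-6, 10.1, 9.9),
               hit = c(FALSE, TRUE, TRUE, FALSE), id = "SIRS_WBC"),
    data.frame(kind = "SYSTOLIC_BP", value = c(90, 90 - eps, 90 + 1e-6, 91),
               hit = c(TRUE, TRUE, FALSE, FALSE), id = "SHOCK_SBP"),
    data.frame(kind = "LACTATE", value = c(2.0, 2.0 + eps, 2.0 - 1e-6),
               hit = c(TRUE, TRUE, FALSE), id = "SHOCK_LACTATE")
  )
}
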