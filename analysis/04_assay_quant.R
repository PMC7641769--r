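#!/usr/bin/env Rscript
# Closed-form assay quantifications: fiber tract statistics at the study
# design, growth doubling times, helicase unwinding, CD normalization and
# qPCR-stop relative amplification. Output under results/assays/.

suppressMessages(library(g4pombe))
out <- "results/assays"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Fiber tracts: n = 17 control vs n = 50 treated, one-third mean reduction.
tracts <- gen_tract_sample(sim_config(seed = 14))
st <- tract_stats(tracts$samples_um, control = "control")
print(st)
write_tsv(as.data.frame(st), file.path(out, "tract_stats.tsv"))

# Doubling times for three cultures counted after 12 h.
growth <- data.frame(condition = c("dmso", "phendc3_20uM", "phendc3_50uM"),
                     x0 = 1e6,
                     x = c(2^(720 / 168), 2^(720 / 162), 2^(720 / 185)) * 1e6)
growth$doubling_min <- doubling_time(12, growth$x0, growth$x, "minutes")
print(growth)
write_tsv(growth, file.path(out, "doubling_times.tsv"))

# Helicase titration: unwound fraction per band pair.
bands <- data.frame(pfh1_nM = c(0, 0.09, 0.9, 9, 18),
                    P = c(2, 10, 38, 62, 70), S = c(98, 90, 62, 38, 25))
bands$percent_unwound <- percent_unwound(bands$P, bands$S)
print(bands)
write_tsv(bands, file.path(out, "unwinding.tsv"))

# CD normalization of a millidegree spectrum to molar ellipticity.
cd <- data.frame(wavelength_nm = seq(220, 320, by = 20),
                 m_deg = c(-2.1, 0.8, 6.4, 3.0, 0.7, -0.2))
cd$molar_ellipticity <- molar_ellipticity(cd$m_deg, M = 7900, L = 0.1, C = 30)
write_tsv(cd, file.path(out, "cd_normalized.tsv"))

# qPCR stop assay: G4 target vs non-G4 reference across conditions.
cq <- expand.grid(target = c("g4_site", "ade6"),
                  condition = c("dmso", "kcl", "kcl_phendc3"),
                  stringsAsFactors = FALSE)
cq$cq <- c(20.1, 20.0, 22.4, 20.1, 26.8, 20.3)
ra <- relative_amplification(cq, reference_target = "ade6",
                             control_condition = "dmso")
print(ra)
write_tsv(as.data.frame(ra), file.path(out, "qpcr_relative_amplification.tsv"))
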