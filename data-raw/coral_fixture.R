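# Generates inst/extdata/coral_symbionts_synthetic.csv, a synthetic
# surrogate for a Caribbean coral-symbiont survey: six host groups (one
# coral taxon split across two depths), six symbiont species columns, nine
# scored host-symbiont pairs.  Group sizes and observed prevalences emulate
# a survey in which the 104-colony host was sampled sufficiently while the
# 35-colony host was not; the fanworm column on that host is scored on only
# 18 colonies at mid prevalence, so its curve cannot complete a stability
# window within the available effort.
library(prevstab)

spec <- data.frame(
  group = c("Acropora palmata", "Acropora palmata",
            "Agaricia agaricites", "Agaricia lamarcki",
            "Millepora complanata", "Millepora complanata",
            "Millepora complanata",
            "Orbicella faveolata 6m", "Orbicella faveolata 15m"),
  species = c("Domecia acanthophora", "Spirobranchus polycerus",
              "Opecarcinus hypostegus", "Opecarcinus hypostegus",
              "Megabalanus stultus", "Domecia acanthophora",
              "Acanthemblemaria spinosa",
              "Troglocarcinus corallicola", "Troglocarcinus corallicola"),
  k_max = c(35, 18, 60, 44, 104, 104, 104, 50, 52),
  ones  = c(12,  8, 27, 31,  25,  20,  22, 18, 11),
  stringsAsFactors = FALSE)

tab <- make_fixture_table(spec, seed = 20220324)
df <- data.frame(host = tab$group, tab$values, check.names = FALSE)
write.csv(df, "inst/extdata/coral_symbionts_synthetic.csv",
          row.names = FALSE, na = "")
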