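# Shared fixtures: a tiny handcrafted quarter, small generator configs,
# and a minimal cohort constructor for statistics-level tests.

write_tiny_quarter <- function(dir = tempfile("quarter")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(file, lines) {
    writeLines(lines, file.path(dir, file))
  }
  w("DEMO.txt", c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$wt$wt_cod$occp_cod$occr_country",
    "101$1$20230201$20230111$F$70$YR$81$KG$MD$US",
    "102$2$20230215$20230120$M$150$MON$110$LBS$CN$JP",
    "103$3$202303$$UNK$$$$$OT$FR"
  ))
  w("DRUG.txt", c(
    "primaryid$drug_seq$drugname$role_cod",
    "101$1$PROGRAF$PS",
    "101$2$aspirin$C",
    "102$1$ Cyclosporine $PS",
    "102$2$tacrolimus$C",
    "103$1$ibuprofen$PS"
  ))
  w("REAC.txt", c(
    "primaryid$pt",
    "101$Proteinuria",
    "101$Headache",
    "102$Acute kidney injury",
    "102$ACUTE KIDNEY INJURY",
    "102$Nausea"
  ))
  w("OUTC.txt", c(
    "primaryid$outc_cod",
    "101$HO",
    "102$DE",
    "102$HO"
  ))
  w("THER.txt", c(
    "primaryid$dsg_drug_seq$start_dt$end_dt",
    "101$1$20230101$",
    "102$1$20230301$",
    "102$1$20230110$"
  ))
  w("INDI.txt", c(
    "primaryid$indi_drug_seq$indi_pt",
    "101$1$Renal transplant",
    "102$1$Systemic lupus erythematosus"
  ))
  dir
}

tiny_lexicon <- function() {
  list(
    tacrolimus = c("tacrolimus", "prograf"),
    cyclosporine = c("cyclosporine", "neoral")
  )
}

tiny_smq <- function() {
  smq_definition("renal fixture", c("Proteinuria", "Acute kidney injury",
                                    "Renal failure"))
}

# One study drug, one event PT, sized for fast replicate loops.
small_recovery_config <- function(rho = 2.586, n_reports = 2000,
                                  duplicate_rate = 0, seed = 1) {
  synthetic_config(
    n_reports = n_reports,
    drugs = tibble::tibble(drug = "drugx", exposure_prob = 0.15, rho = rho,
                           onset_scale = 100, onset_shape = 1),
    background_drugs = tibble::tibble(drug = c("bga", "bgb"),
                                      exposure_prob = c(0.3, 0.3)),
    events = tibble::tibble(pt = "proteinuria", baseline_prob = 0.08),
    background_events = tibble::tibble(pt = c("nausea", "headache"),
                                       baseline_prob = c(0.3, 0.2)),
    duplicate_rate = duplicate_rate,
    seed = seed
  )
}

# Minimal cohort for statistics-level operations, bypassing parsing.
make_mini_cohort <- function(exposed, event, reactions = NULL,
                             drug = "drugx", ...) {
  n <- length(exposed)
  if (is.null(reactions)) {
    reactions <- lapply(event, function(e) if (e) "pt1" else character())
  }
  extra <- list(...)
  cohort <- tibble::tibble(
    primary_id = seq_len(n),
    case_id = seq_len(n),
    event = event,
    reactions = reactions,
    matched_pts = lapply(seq_len(n), function(i) {
      if (event[i]) reactions[[i]] else character()
    }),
    drug_names = lapply(seq_len(n), function(i) {
      if (exposed[i]) drug else "otherdrug"
    })
  )
  cohort[[paste0("exposed_", drug)]] <- exposed
  for (nm in names(extra)) cohort[[nm]] <- extra[[nm]]
  attr(cohort, "drugs") <- drug
  attr(cohort, "smq_name") <- "mini smq"
  class(cohort) <- c("faers_cohort", class(cohort))
  cohort
}

# Expand a 2x2 table into a per-report data frame with a binary covariate.
expand_two_by_two <- function(n0_noevent, n0_event, n1_noevent, n1_event,
                              levels = c("F", "M")) {
  tibble::tibble(
    event = c(rep(0L, n0_noevent), rep(1L, n0_event),
              rep(0L, n1_noevent), rep(1L, n1_event)),
    x = factor(c(rep(levels[1], n0_noevent + n0_event),
                 rep(levels[2], n1_noevent + n1_event)), levels = levels)
  )
}
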