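# in-code fixture builders: small FAERS case sets assembled row by row

demo_row <- function(primaryid, caseid, fda_dt = NA, event_dt = NA,
                     sex = NA, age = NA, age_cod = NA, wt = NA,
                     wt_cod = NA, reporter_country = NA) {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = as.character(fda_dt),
             event_dt = as.character(event_dt),
             sex = as.character(sex), age = as.character(age),
             age_cod = as.character(age_cod), wt = as.character(wt),
             wt_cod = as.character(wt_cod),
             reporter_country = as.character(reporter_country),
             stringsAsFactors = FALSE)
}

drug_row <- function(primaryid, drugname, role_cod = "PS", drug_seq = "1",
                     prod_ai = NA) {
  data.frame(primaryid = as.character(primaryid),
             drug_seq = as.character(drug_seq),
             role_cod = as.character(role_cod),
             drugname = as.character(drugname),
             prod_ai = as.character(prod_ai), stringsAsFactors = FALSE)
}

reac_row <- function(primaryid, pt) {
  data.frame(primaryid = as.character(primaryid), pt = as.character(pt),
             stringsAsFactors = FALSE)
}

ther_row <- function(primaryid, start_dt = NA, dsg_drug_seq = "1") {
  data.frame(primaryid = as.character(primaryid),
             dsg_drug_seq = as.character(dsg_drug_seq),
             start_dt = as.character(start_dt), stringsAsFactors = FALSE)
}

empty_tab <- function(schema) {
  cols <- faers_schema_columns(schema)
  as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                stringsAsFactors = FALSE)
}

# a minimal two-report set: one target report (PS TEPEZZA) and one
# background report
tiny_cases <- function() {
  demo <- rbind(demo_row(101, 1, fda_dt = "20200301", sex = "F"),
                demo_row(201, 2, fda_dt = "20210415", sex = "M"))
  drug <- rbind(drug_row(101, "TEPEZZA"),
                drug_row(201, "OTHER DRUG"))
  reac <- rbind(reac_row(101, "Nausea"), reac_row(101, "Headache"),
                reac_row(201, "Nausea"))
  join_cases(demo, drug, reac, empty_tab("THER"))
}

# random pair records for property checks
random_pairs <- function(n, n_pt = 6, target_frac = 0.3) {
  data.frame(caseid = as.character(seq_len(n)),
             primaryid = as.character(seq_len(n)),
             pt = sample(LETTERS[seq_len(n_pt)], n, replace = TRUE),
             soc = "SOC", is_target = runif(n) < target_frac,
             stringsAsFactors = FALSE)
}
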