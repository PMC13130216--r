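# Reading, writing and cohorting of FAERS-style quarterly ASCII tables.
#
# The quarterly dialect is '$'-delimited text with a header row, one file
# per sub-table: DEMO (one row per report version), DRUG, REAC, OUTC,
# THER, INDI (zero or more rows per report, joined on primaryid).

faers_files <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI")

read_dollar_file <- function(path) {
  if (!file.exists(path)) {
    stop("FAERS file not found: ", path, call. = FALSE)
  }
  out <- readr::read_delim(
    path,
    delim = "$", quote = "", trim_ws = TRUE,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"),
    progress = FALSE, show_col_types = FALSE
  )
  names(out) <- tolower(names(out))
  out
}

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(
      "FAERS parse error: file '", file, "' is missing mandatory column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(df)
}

first_existing <- function(df, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0) NULL else df[[hit[[1]]]]
}

numeric_id <- function(x) {
  suppressWarnings(as.numeric(stringr::str_trim(as.character(x))))
}

# Split a child table into a list-column aligned with `pids`, one element
# per report.  Splitting a plain data.frame is markedly faster than a
# tibble, and generator/parser loops lean on this.
split_by_pid <- function(df, pids) {
  f <- factor(df$primary_id, levels = pids)
  keep <- !is.na(f)
  f <- f[keep]
  cols <- setdiff(names(df), "primary_id")
  parts <- lapply(cols, function(cl) split(df[[cl]][keep], f))
  names(parts) <- cols
  ns <- tabulate(f, nbins = length(pids))
  lapply(seq_along(pids), function(i) {
    structure(lapply(parts, function(p) p[[i]]),
              names = cols, class = "data.frame",
              row.names = if (ns[i] > 0) seq_len(ns[i]) else integer())
  })
}

# Inverse of split_by_pid: flatten a list-column of data frames back to a
# long table with a primary_id key, without binding thousands of pieces.
# assemble_reports() caches the original long tables; the cache survives
# row subsetting (deduplication) because it is filtered by primary_id.
long_from_listcol <- function(reports, col) {
  cache <- attr(reports, "long_cache")[[col]]
  if (!is.null(cache)) {
    return(cache[cache$primary_id %in% reports$primary_id, , drop = FALSE])
  }
  pieces <- reports[[col]]
  n <- vapply(pieces, NROW, integer(1))
  cols <- names(pieces[[which.max(n > 0)[1]]] %||% pieces[[1]])
  out <- lapply(cols, function(cl) {
    unlist(lapply(pieces, function(p) p[[cl]]), use.names = FALSE)
  })
  names(out) <- cols
  out$primary_id <- rep(reports$primary_id, n)
  # date columns lose their class through unlist
  for (cl in cols) {
    if (inherits(pieces[[1]][[cl]], "Date")) {
      out[[cl]] <- as.Date(out[[cl]], origin = "1970-01-01")
    }
  }
  tibble::as_tibble(out)
}

empty_drugs <- function() tibble::tibble(seq = integer(), name = character(), role = character())
empty_therapies <- function() {
  tibble::tibble(drug_seq = integer(),
                 start_date = as.Date(character()), end_date = as.Date(character()))
}
empty_indications <- function() tibble::tibble(drug_seq = integer(), pt = character())

# Assemble normalised long tables into one report per row.  Shared by the
# file parser and the synthetic generator so both produce byte-identical
# shapes.
assemble_reports <- function(demo, drug, reac, outc, ther, indi, log = list()) {
  pids <- demo$primary_id
  split_vec <- function(df, col) {
    f <- factor(df$primary_id, levels = pids)
    unname(split(df[[col]][!is.na(f)], f[!is.na(f)]))
  }
  reports <- tibble::new_tibble(list(
    primary_id = demo$primary_id,
    case_id = demo$case_id,
    fda_date = demo$fda_date,
    event_date = demo$event_date,
    sex = demo$sex,
    age_years = demo$age_years,
    weight_kg = demo$weight_kg,
    reporter = demo$reporter,
    country = demo$country,
    drugs = split_by_pid(drug, pids),
    reactions = split_vec(reac, "pt"),
    outcomes = split_vec(outc, "code"),
    therapies = split_by_pid(ther, pids),
    indications = split_by_pid(indi, pids)
  ), nrow = length(pids))
  n_noreac <- sum(lengths(reports$reactions) == 0)
  if (n_noreac > 0) {
    log <- c(log, list(tibble::tibble(
      file = "REAC", issue = "report with no reaction rows", n = n_noreac
    )))
  }
  attr(reports, "parse_log") <- dplyr::bind_rows(log)
  attr(reports, "long_cache") <- list(
    drugs = tibble::as_tibble(drug),
    therapies = tibble::as_tibble(ther),
    indications = tibble::as_tibble(indi)
  )
  class(reports) <- c("faers_reports", class(reports))
  reports
}

#' Parse a FAERS-style quarter into report records
#'
#' Reads the six `'$'`-delimited sub-tables of a quarterly release and
#' joins them on `primaryid` into a tibble with one row per report version
#' and list-columns for drugs, reactions, outcomes, therapy dates and
#' indications.  Unknown columns are ignored; malformed rows (non-numeric
#' identifiers, invalid codes) are dropped or blanked and counted in the
#' `parse_log` attribute rather than aborting the run.
#'
#' @param dir Directory containing `DEMO.txt`, `DRUG.txt`, `REAC.txt`,
#'   `OUTC.txt`, `THER.txt`, `INDI.txt`.  Individual paths may be
#'   overridden.
#' @param demo,drug,reac,outc,ther,indi Paths to the six tables.
#' @return A `faers_reports` tibble.  Attributes: `parse_log`, a tibble of
#'   counted anomalies.
#' @export
#' @examples
#' qdir <- tempfile()
#' cfg <- synthetic_config(n_reports = 50, seed = 1)
#' write_faers_quarter(simulate_reports(cfg), qdir)
#' reports <- read_faers_quarter(qdir)
#' nrow(reports)
read_faers_quarter <- function(dir = NULL,
                               demo = file.path(dir, "DEMO.txt"),
                               drug = file.path(dir, "DRUG.txt"),
                               reac = file.path(dir, "REAC.txt"),
                               outc = file.path(dir, "OUTC.txt"),
                               ther = file.path(dir, "THER.txt"),
                               indi = file.path(dir, "INDI.txt")) {
  log <- list()
  note <- function(file, issue, n) {
    if (n > 0) log[[length(log) + 1]] <<- tibble::tibble(file = file, issue = issue, n = n)
  }

  demo_raw <- read_dollar_file(demo)
  require_columns(demo_raw, c("primaryid", "caseid"), demo)
  pid <- numeric_id(demo_raw$primaryid)
  cid <- numeric_id(demo_raw$caseid)
  bad <- is.na(pid) | is.na(cid) | pid <= 0 | cid <= 0
  note("DEMO", "row with missing/invalid primaryid or caseid", sum(bad))
  demo_raw <- demo_raw[!bad, , drop = FALSE]
  pid <- pid[!bad]
  cid <- cid[!bad]
  dup <- duplicated(pid)
  note("DEMO", "duplicate primaryid (first kept)", sum(dup))
  demo_raw <- demo_raw[!dup, , drop = FALSE]
  pid <- pid[!dup]
  cid <- cid[!dup]

  fda <- parse_faers_date(first_existing(demo_raw, "fda_dt"))
  evt <- parse_faers_date(first_existing(demo_raw, "event_dt"))
  sex_raw <- toupper(stringr::str_trim(
    first_existing(demo_raw, c("sex", "gndr_cod")) %||% rep(NA_character_, nrow(demo_raw))
  ))
  demo_tbl <- tibble::tibble(
    primary_id = pid,
    case_id = cid,
    fda_date = fda$date,
    # partial event dates are kept as missing: onset needs day precision
    event_date = dplyr::if_else(evt$full, evt$date, as.Date(NA)),
    sex = dplyr::if_else(sex_raw %in% c("F", "M"), sex_raw, "unknown", missing = "unknown"),
    age_years = convert_age_years(
      first_existing(demo_raw, "age") %||% rep(NA_character_, nrow(demo_raw)),
      first_existing(demo_raw, "age_cod") %||% rep(NA_character_, nrow(demo_raw))
    ),
    weight_kg = convert_weight_kg(
      first_existing(demo_raw, "wt") %||% rep(NA_character_, nrow(demo_raw)),
      first_existing(demo_raw, "wt_cod") %||% rep(NA_character_, nrow(demo_raw))
    ),
    reporter = map_reporter_code(
      first_existing(demo_raw, "occp_cod") %||% rep(NA_character_, nrow(demo_raw))
    ),
    country = toupper(stringr::str_trim(
      first_existing(demo_raw, c("occr_country", "reporter_country")) %||%
        rep(NA_character_, nrow(demo_raw))
    ))
  )
  demo_tbl$country[!is.na(demo_tbl$country) & nchar(demo_tbl$country) != 2L] <- NA_character_

  drug_raw <- read_dollar_file(drug)
  require_columns(drug_raw, c("primaryid", "drugname"), drug)
  role <- toupper(stringr::str_trim(
    first_existing(drug_raw, "role_cod") %||% rep(NA_character_, nrow(drug_raw))
  ))
  bad_role <- !is.na(role) & !(role %in% c("PS", "SS", "C", "I"))
  note("DRUG", "unknown role_cod (blanked)", sum(bad_role))
  role[bad_role] <- NA_character_
  drug_tbl <- tibble::tibble(
    primary_id = numeric_id(drug_raw$primaryid),
    seq = suppressWarnings(as.integer(numeric_id(
      first_existing(drug_raw, c("drug_seq", "dsg_drug_seq")) %||%
        seq_len(nrow(drug_raw))
    ))),
    name = stringr::str_trim(drug_raw$drugname),
    role = role
  )
  drug_tbl <- drug_tbl[!is.na(drug_tbl$primary_id) & !is.na(drug_tbl$name), , drop = FALSE]

  reac_raw <- read_dollar_file(reac)
  require_columns(reac_raw, c("primaryid", "pt"), reac)
  reac_tbl <- tibble::tibble(
    primary_id = numeric_id(reac_raw$primaryid),
    pt = stringr::str_trim(reac_raw$pt)
  )
  reac_tbl <- reac_tbl[!is.na(reac_tbl$primary_id) & !is.na(reac_tbl$pt) &
                         reac_tbl$pt != "", , drop = FALSE]

  outc_raw <- read_dollar_file(outc)
  require_columns(outc_raw, c("primaryid", "outc_cod"), outc)
  ocode <- toupper(stringr::str_trim(outc_raw$outc_cod))
  bad_out <- !is.na(ocode) & !(ocode %in% outcome_codes)
  note("OUTC", "unknown outc_cod (dropped)", sum(bad_out))
  outc_tbl <- tibble::tibble(
    primary_id = numeric_id(outc_raw$primaryid),
    code = ocode
  )
  outc_tbl <- outc_tbl[!is.na(outc_tbl$primary_id) & !bad_out & !is.na(ocode), , drop = FALSE]

  ther_raw <- read_dollar_file(ther)
  require_columns(ther_raw, "primaryid", ther)
  start <- parse_faers_date(first_existing(ther_raw, "start_dt") %||%
                              rep(NA_character_, nrow(ther_raw)))
  end <- parse_faers_date(first_existing(ther_raw, "end_dt") %||%
                            rep(NA_character_, nrow(ther_raw)))
  ther_tbl <- tibble::tibble(
    primary_id = numeric_id(ther_raw$primaryid),
    drug_seq = suppressWarnings(as.integer(numeric_id(
      first_existing(ther_raw, c("dsg_drug_seq", "drug_seq")) %||%
        rep(NA_character_, nrow(ther_raw))
    ))),
    start_date = dplyr::if_else(start$full, start$date, as.Date(NA)),
    end_date = dplyr::if_else(end$full, end$date, as.Date(NA))
  )
  ther_tbl <- ther_tbl[!is.na(ther_tbl$primary_id), , drop = FALSE]
  bad_span <- !is.na(ther_tbl$start_date) & !is.na(ther_tbl$end_date) &
    ther_tbl$start_date > ther_tbl$end_date
  note("THER", "therapy start after end (dates blanked)", sum(bad_span))
  ther_tbl$start_date[bad_span] <- as.Date(NA)
  ther_tbl$end_date[bad_span] <- as.Date(NA)

  indi_raw <- read_dollar_file(indi)
  require_columns(indi_raw, "primaryid", indi)
  indi_tbl <- tibble::tibble(
    primary_id = numeric_id(indi_raw$primaryid),
    drug_seq = suppressWarnings(as.integer(numeric_id(
      first_existing(indi_raw, c("indi_drug_seq", "drug_seq")) %||%
        rep(NA_character_, nrow(indi_raw))
    ))),
    pt = stringr::str_trim(first_existing(indi_raw, "indi_pt") %||%
                             rep(NA_character_, nrow(indi_raw)))
  )
  indi_tbl <- indi_tbl[!is.na(indi_tbl$primary_id) & !is.na(indi_tbl$pt), , drop = FALSE]

  assemble_reports(demo_tbl, drug_tbl, reac_tbl, outc_tbl, ther_tbl, indi_tbl, log)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write report records as a FAERS-style ASCII quarter
#'
#' Serialises a `faers_reports` tibble back to the six `'$'`-delimited
#' files, so that a parsed (or simulated) batch round-trips through
#' [read_faers_quarter()].
#'
#' @param reports A `faers_reports` tibble.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_faers_quarter <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- reports$primary_id
  demo <- tibble::tibble(
    primaryid = pid,
    caseid = reports$case_id,
    fda_dt = format_faers_date(reports$fda_date),
    event_dt = format_faers_date(reports$event_date),
    sex = dplyr::if_else(reports$sex %in% c("F", "M"), reports$sex, NA_character_),
    age = reports$age_years,
    age_cod = dplyr::if_else(is.na(reports$age_years), NA_character_, "YR"),
    wt = reports$weight_kg,
    wt_cod = dplyr::if_else(is.na(reports$weight_kg), NA_character_, "KG"),
    occp_cod = dplyr::case_when(
      reports$reporter == "physician" ~ "MD",
      reports$reporter == "pharmacist" ~ "PH",
      reports$reporter == "other_health" ~ "OT",
      reports$reporter == "consumer" ~ "CN",
      TRUE ~ NA_character_
    ),
    occr_country = reports$country
  )
  drug <- long_from_listcol(reports, "drugs")
  drug <- tibble::tibble(primaryid = drug$primary_id, drug_seq = drug$seq,
                         drugname = drug$name, role_cod = drug$role)
  reac <- tibble::tibble(
    primaryid = rep(pid, lengths(reports$reactions)),
    pt = unlist(reports$reactions, use.names = FALSE) %||% character()
  )
  outc <- tibble::tibble(
    primaryid = rep(pid, lengths(reports$outcomes)),
    outc_cod = unlist(reports$outcomes, use.names = FALSE) %||% character()
  )
  ther <- long_from_listcol(reports, "therapies")
  ther <- tibble::tibble(primaryid = ther$primary_id, dsg_drug_seq = ther$drug_seq,
                         start_dt = format_faers_date(ther$start_date),
                         end_dt = format_faers_date(ther$end_date))
  indi <- long_from_listcol(reports, "indications")
  indi <- tibble::tibble(primaryid = indi$primary_id, indi_drug_seq = indi$drug_seq,
                         indi_pt = indi$pt)
  files <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                THER = ther, INDI = indi)
  for (nm in names(files)) {
    readr::write_delim(files[[nm]], file.path(dir, paste0(nm, ".txt")),
                       delim = "$", na = "")
  }
  invisible(dir)
}

#' Deduplicate case report versions
#'
#' Applies the FDA-recommended rule for spontaneous-report databases: a
#' case may be submitted repeatedly; among versions sharing a `case_id`
#' the one with the latest FDA receipt date is retained, and among
#' versions tied on receipt date the highest `primary_id` wins.  The
#' survivor therefore maximises `(fda_date, primary_id)` lexicographically
#' and is independent of input order.
#'
#' @param reports A `faers_reports` tibble (or any tibble with
#'   `case_id`, `fda_date`, `primary_id` columns).
#' @return A tibble with exactly one row per `case_id`.
#' @export
dedupe_reports <- function(reports) {
  if (nrow(reports) == 0) {
    return(reports)
  }
  ord <- order(reports$case_id,
               dplyr::coalesce(reports$fda_date, as.Date("0001-01-01")),
               reports$primary_id)
  sorted <- reports[ord, , drop = FALSE]
  keep <- !duplicated(sorted$case_id, fromLast = TRUE)
  out <- sorted[keep, , drop = FALSE]
  attr(out, "parse_log") <- attr(reports, "parse_log")
  attr(out, "long_cache") <- attr(reports, "long_cache")
  attr(out, "truth") <- attr(reports, "truth")
  out
}

#' Read an SMQ preferred-term list
#'
#' One PT per line, UTF-8, `#` comments allowed.  Terms are case-folded
#' and de-duplicated on load.
#'
#' @param path Path to the PT list.
#' @param name Label for the query.
#' @param scope `"broad"` or `"narrow"`.
#' @return An `smq_definition` object.
#' @export
read_smq <- function(path, name = basename(path), scope = c("broad", "narrow")) {
  scope <- match.arg(scope)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringr::str_trim(sub("#.*$", "", lines))
  pts <- unique(fold_term(lines[lines != ""]))
  smq_definition(name, pts, scope)
}

#' Construct an SMQ definition from a PT vector
#'
#' @param name Label for the query.
#' @param pts Character vector of preferred terms (case-folded on
#'   construction; must be non-empty).
#' @param scope `"broad"` or `"narrow"`.
#' @return An `smq_definition` object.
#' @export
smq_definition <- function(name, pts, scope = c("broad", "narrow")) {
  scope <- match.arg(scope)
  pts <- unique(fold_term(pts))
  pts <- pts[!is.na(pts) & pts != ""]
  if (length(pts) == 0) {
    stop("An SMQ definition needs at least one preferred term.", call. = FALSE)
  }
  structure(list(name = name, scope = scope, pts = pts), class = "smq_definition")
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("<smq_definition> ", x$name, " (", x$scope, "), ",
      length(x$pts), " PTs\n", sep = "")
  invisible(x)
}

#' Read a drug lexicon
#'
#' YAML mapping from study-drug key to the generic and brand names that
#' should be recognised in the free-text `drugname` field.
#'
#' @param path Path to a YAML file, e.g. `tacrolimus: [tacrolimus, prograf]`.
#' @return Named list of character vectors.
#' @export
read_drug_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  validate_lexicon(lex)
}

validate_lexicon <- function(lexicon) {
  if (!is.list(lexicon) || length(lexicon) == 0 || is.null(names(lexicon)) ||
      any(names(lexicon) == "")) {
    stop("Drug lexicon configuration error: expected a non-empty named ",
         "list of drug-name vectors.", call. = FALSE)
  }
  lapply(lexicon, function(x) {
    x <- fold_term(unlist(x))
    x <- x[!is.na(x) & x != ""]
    if (length(x) == 0) {
      stop("Drug lexicon configuration error: a study drug has no names.",
           call. = FALSE)
    }
    unique(x)
  })
}

lexicon_long <- function(lexicon) {
  lexicon <- validate_lexicon(lexicon)
  tibble::tibble(
    drug = rep(names(lexicon), lengths(lexicon)),
    name_folded = unlist(lexicon, use.names = FALSE)
  )
}

#' Flag study-drug exposure for each report
#'
#' A report counts as exposed to a study drug when any of its drug entries
#' matches a lexicon name after case-folding and whitespace trimming AND
#' the entry's role code is in `roles` (default: primary suspect only).
#'
#' @param reports A `faers_reports` tibble.
#' @param lexicon Named list mapping drug key to name strings (or a path
#'   readable by [read_drug_lexicon()]).
#' @param roles FAERS role codes that qualify as exposure.
#' @return Tibble with `primary_id` plus one logical column per drug key.
#' @export
match_drugs <- function(reports, lexicon, roles = "PS") {
  lex <- lexicon_long(lexicon)
  keys <- unique(lex$drug)
  long <- long_from_listcol(reports, "drugs")
  out <- tibble::as_tibble(setNames(
    rep(list(logical(nrow(reports))), length(keys)), keys
  ))
  if (nrow(long) > 0) {
    long <- long[!is.na(long$role) & long$role %in% roles, , drop = FALSE]
    long$name_folded <- fold_term(long$name)
    hits <- dplyr::inner_join(long, lex, by = "name_folded",
                              relationship = "many-to-many")
    for (k in keys) {
      out[[k]] <- reports$primary_id %in% hits$primary_id[hits$drug == k]
    }
  }
  dplyr::bind_cols(tibble::tibble(primary_id = reports$primary_id), out)
}

#' Match a report's reactions against an SMQ
#'
#' @param reactions Character vector of reaction PTs (verbatim).
#' @param smq An `smq_definition`.
#' @return Character vector: the case-folded PTs present in the SMQ
#'   (set semantics -- repeats collapse).
#' @export
map_smq <- function(reactions, smq) {
  stopifnot(inherits(smq, "smq_definition"))
  intersect(fold_term(reactions), smq$pts)
}

#' Default indication-to-group mapping
#'
#' Maps common indication PTs to the three analysis groups used for the
#' risk-factor models: `autoimmune` (reference), `transplant`, `other`.
#' Indication terms present on a report but absent from the map fall into
#' `other`; reports without any indication are missing.
#'
#' @return Tibble with columns `pt` (folded) and `group`.
#' @export
default_indication_groups <- function() {
  tibble::tibble(
    pt = c(
      "systemic lupus erythematosus", "lupus nephritis", "rheumatoid arthritis",
      "psoriasis", "atopic dermatitis", "nephrotic syndrome",
      "dermatomyositis", "ulcerative colitis", "crohn's disease",
      "myasthenia gravis", "uveitis", "aplastic anaemia",
      "renal transplant", "kidney transplant", "liver transplant",
      "heart transplant", "lung transplant", "bone marrow transplant",
      "stem cell transplant", "cardiac transplant",
      "transplant rejection prophylaxis", "graft versus host disease"
    ),
    group = c(rep("autoimmune", 12), rep("transplant", 10))
  )
}

indication_group_levels <- c("autoimmune", "transplant", "other")

#' Build the analysis cohort table
#'
#' One row per (deduplicated) report carrying: per-drug exposure flags
#' (`exposed_<key>`), the SMQ event flag and matched PTs, binned
#' covariates, outcome codes, folded reaction and drug-name sets, and
#' per-drug time-to-onset in days (event date minus the earliest therapy
#' start date among entries whose `drug_seq` maps to a matched drug
#' entry; negative intervals are treated as missing and counted in the
#' `onset_anomalies` attribute).
#'
#' @param reports Deduplicated `faers_reports`.
#' @param lexicon Drug lexicon (named list).
#' @param smq An `smq_definition`.
#' @param roles Role codes qualifying as exposure (default primary
#'   suspect).
#' @param indication_map Tibble `pt`/`group` mapping indication PTs to
#'   covariate groups; see [default_indication_groups()].
#' @return A `faers_cohort` tibble.  Attributes: `drugs` (study-drug
#'   keys), `roles`, `smq_name`, `onset_anomalies`.
#' @export
build_cohort <- function(reports, lexicon, smq, roles = "PS",
                         indication_map = default_indication_groups()) {
  stopifnot(inherits(smq, "smq_definition"))
  lexicon <- validate_lexicon(lexicon)
  keys <- names(lexicon)
  exposure <- match_drugs(reports, lexicon, roles = roles)

  # fold all reactions in one vectorised pass, then re-split per report
  ridx <- factor(rep(seq_len(nrow(reports)), lengths(reports$reactions)),
                 levels = seq_len(nrow(reports)))
  rfold <- fold_term(unlist(reports$reactions, use.names = FALSE))
  reactions_f <- lapply(unname(split(rfold, ridx)), unique)
  matched <- lapply(reactions_f, intersect, y = smq$pts)

  drug_long <- long_from_listcol(reports, "drugs")
  drug_long <- drug_long[!is.na(drug_long$role) & drug_long$role %in% roles, ,
                         drop = FALSE]
  drug_long$name_folded <- fold_term(drug_long$name)
  drug_names <- split(drug_long$name_folded,
                      factor(drug_long$primary_id, levels = reports$primary_id))
  drug_names <- lapply(unname(drug_names), unique)

  # indication group: best-priority mapped group among the report's
  # indication PTs; unmapped terms -> "other"; no indications -> NA
  il <- long_from_listcol(reports, "indications")
  ind_group <- rep(NA_character_, nrow(reports))
  if (nrow(il) > 0) {
    g <- indication_map$group[match(fold_term(il$pt), indication_map$pt)]
    g[is.na(g)] <- "other"
    pr <- match(g, indication_group_levels)
    best <- tapply(pr, factor(il$primary_id, levels = reports$primary_id), min)
    ind_group <- indication_group_levels[as.integer(best)]
  }

  cohort <- tibble::tibble(
    primary_id = reports$primary_id,
    case_id = reports$case_id,
    fda_date = reports$fda_date,
    year = as.integer(format(reports$fda_date, "%Y")),
    event_date = reports$event_date,
    sex = dplyr::if_else(reports$sex %in% c("F", "M"), reports$sex, NA_character_),
    age_years = reports$age_years,
    age_bin = bin_age(reports$age_years),
    weight_kg = reports$weight_kg,
    weight_bin = bin_weight(reports$weight_kg),
    reporter = reports$reporter,
    country = reports$country,
    indication_group = factor(ind_group, levels = indication_group_levels),
    outcomes = reports$outcomes,
    outcome_group = factor(vapply(reports$outcomes, outcome_group, character(1)),
                           levels = outcome_group_levels),
    reactions = reactions_f,
    drug_names = drug_names,
    matched_pts = matched,
    event = lengths(matched) > 0
  )
  for (k in keys) {
    cohort[[paste0("exposed_", k)]] <- exposure[[k]]
  }

  # per-drug onset: earliest therapy start among matched drug entries
  anomalies <- 0L
  ther_long <- long_from_listcol(reports, "therapies")
  lex_long <- lexicon_long(lexicon)
  for (k in keys) {
    onset_col <- rep(NA_real_, nrow(cohort))
    if (nrow(drug_long) > 0 && nrow(ther_long) > 0) {
      seqs <- drug_long[drug_long$name_folded %in%
                          lex_long$name_folded[lex_long$drug == k],
                        c("primary_id", "seq")]
      ther_k <- dplyr::inner_join(
        ther_long, seqs,
        by = c("primary_id" = "primary_id", "drug_seq" = "seq")
      )
      ther_k <- ther_k[!is.na(ther_k$start_date), , drop = FALSE]
      if (nrow(ther_k) > 0) {
        starts <- dplyr::summarise(
          dplyr::group_by(ther_k, .data$primary_id),
          start = min(.data$start_date), .groups = "drop"
        )
        idx <- match(starts$primary_id, cohort$primary_id)
        onset <- as.numeric(cohort$event_date[idx] - starts$start)
        neg <- !is.na(onset) & onset < 0
        anomalies <- anomalies + sum(neg)
        onset[neg] <- NA_real_
        onset_col[idx] <- onset
      }
    }
    onset_col[!cohort[[paste0("exposed_", k)]]] <- NA_real_
    cohort[[paste0("onset_", k)]] <- onset_col
  }

  attr(cohort, "drugs") <- keys
  attr(cohort, "roles") <- roles
  attr(cohort, "smq_name") <- smq$name
  attr(cohort, "onset_anomalies") <- anomalies
  class(cohort) <- c("faers_cohort", class(cohort))
  cohort
}

cohort_drugs <- function(cohort) {
  drugs <- attr(cohort, "drugs")
  if (is.null(drugs)) {
    drugs <- sub("^exposed_", "", grep("^exposed_", names(cohort), value = TRUE))
  }
  drugs
}

exposed_flag <- function(cohort, drug) {
  col <- paste0("exposed_", drug)
  if (!col %in% names(cohort)) {
    stop("Unknown study drug '", drug, "' (no column ", col, ").", call. = FALSE)
  }
  cohort[[col]]
}
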