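# Seeded generator of surrogate clinical notes with standoff PHI
# annotations. Two built-in institution styles emulate the cross-institute
# distribution shift: disjoint surface formats for dates/phones/IDs,
# disjoint name/city/street/institute vocabularies, and different carrier
# phrasing. All values are invented surrogates; no real PHI appears
# anywhere.

style_vocab_a <- function() {
  list(
    first_names = c("Marcus", "Elena", "Trevor", "Yolanda", "Deshawn",
                    "Priya", "Colton", "Maribel", "Stefan", "Latoya",
                    "Gavin", "Rosalind", "Dmitri", "Shawna", "Ezekiel",
                    "Paloma", "Harvey", "Noreen", "Quentin", "Tamsin",
                    "Arlo", "Bernice", "Casper", "Delphine"),
    last_names = c("Abernathy", "Castellano", "Driscoll", "Eastwood",
                   "Falkner", "Goldbeck", "Hutchins", "Ibarra", "Jankowski",
                   "Kirkwood", "Lunsford", "Macready", "Northrup",
                   "Okonkwo", "Pemberton", "Quijano", "Rutledge",
                   "Steadman", "Thackeray", "Umberto", "Vanlandingham",
                   "Wexford", "Yarborough", "Zielinski"),
    cities = c("Lakewood Springs", "Marbleton", "Cypress Falls",
               "Eastvale", "Fernwood", "Galloway Bend", "Harmony Grove",
               "Ironwood", "Junction Flats", "Kettle Creek", "Larkspur",
               "Mossy Oak", "Newberry Pines", "Oakhaven", "Pinebluff",
               "Quail Hollow"),
    streets = c("Magnolia Avenue", "Sawgrass Lane", "Colonial Drive",
                "Hickory Court", "Sandpiper Road", "Bayberry Street",
                "Crestview Terrace", "Dogwood Circle", "Eagle Run",
                "Foxglove Way", "Gardenia Boulevard", "Heron Path"),
    institutes = c("North Lake Medical Center", "Riverbend Community Hospital",
                   "Sunrise Orthopedic Institute", "Palmetto Heart Clinic",
                   "Crestwood Surgical Pavilion", "Bluewater Imaging Center",
                   "Magnolia Childrens Hospital", "Lakeside Rehabilitation Campus",
                   "Pine Ridge Cancer Center", "Harborview Family Practice"),
    webs = c("portal.northlakemed.example.org", "www.riverbendhealth.example.com",
             "mychart.sunriseortho.example.net", "results.palmettoheart.example.org"),
    zips = c("32601", "32603", "32605", "32607", "32609", "32611",
             "32614", "32617", "32621", "32627", "32633", "32641"))
}

style_vocab_b <- function() {
  list(
    first_names = c("Ingrid", "Callum", "Beatriz", "Otis", "Fernanda",
                    "Leopold", "Anouk", "Rashid", "Sigrid", "Thaddeus",
                    "Mireille", "Osvaldo", "Petra", "Lazlo", "Wilhelmina",
                    "Jerome", "Odette", "Barnaby", "Celestine", "Ewan",
                    "Franziska", "Gideon", "Henrietta", "Ivo"),
    last_names = c("Ashworth", "Bellweather", "Crankshaw", "Dunmore",
                   "Ellery", "Fairbanks", "Grimaldi", "Hollenbeck",
                   "Innsbruck", "Jarrell", "Kesselring", "Lockhart",
                   "Montrose", "Nightingale", "Oglethorpe", "Pickford",
                   "Quarles", "Ravenscroft", "Sedgewick", "Trowbridge",
                   "Underhill", "Vanderlyn", "Winterbourne", "Yates"),
    cities = c("Alder Heights", "Briarcliff", "Coldwater Junction",
               "Duxbury", "Elmsworth", "Foggy Harbor", "Granite Falls",
               "Hollow Creek", "Inverness Park", "Jade Meadows",
               "Kingfisher Point", "Limestone Ridge", "Mapleton Corners",
               "Norwood Vale", "Ottershaw", "Pelham Crossing"),
    streets = c("Winchester Row", "Abbey Close", "Thistle Lane",
                "Cobblestone Walk", "Juniper Parkway", "Larch Street",
                "Mulberry Mews", "Nettle Court", "Orchard Gate",
                "Primrose Alley", "Quarry Road", "Rosewood Crescent"),
    institutes = c("Saint Alban General Hospital", "Westgate University Clinic",
                   "Northfield Veterans Infirmary", "Cedar Valley Medical Pavilion",
                   "Thornton Memorial Hospital", "Eastbrook Diagnostic Institute",
                   "Grand Mesa Behavioral Health", "Silverlake Womens Center",
                   "Foxhill Pulmonary Associates", "Windmere Dialysis Unit"),
    webs = c("https://charts.stalban.example.edu", "https://portal.westgate.example.edu",
             "https://labs.northfieldvets.example.gov", "https://imaging.cedarvalley.example.edu"),
    zips = c("10302", "10308", "10314", "10319", "10327", "10331",
             "10340", "10346", "10352", "10358", "10363", "10371"))
}

style_templates_a <- function() {
  list(
    DATE = c("Seen in clinic on {PHI} for routine follow up.",
             "Labs were drawn on {PHI} and reviewed with the team.",
             "Last visit on {PHI} went well overall."),
    NAME = c("Discussed the plan with {PHI} at the bedside.",
             "Seen together with {PHI} in attendance.",
             "Care coordinated by {PHI} earlier today."),
    AGE = c("The patient is {PHI} years old with stable disease.",
            "This {PHI} year old returns for interval care."),
    ID = c("Reference record {PHI} for the prior imaging.",
           "Order placed under {PHI} this morning."),
    PHONE = c("Call {PHI} with any new symptoms.",
              "Pharmacy contact {PHI} was confirmed."),
    WEB = c("Portal messages via {PHI} were reviewed."),
    INSTITUTE = c("Records requested from {PHI} for comparison.",
                  "Transferred from {PHI} overnight."),
    STREET = c("Home address listed as {PHI} on file."),
    CITY = c("The patient resides in {PHI} with family."),
    ZIP = c("Mailing zip code {PHI} verified at check in."))
}

style_templates_b <- function() {
  list(
    DATE = c("Encounter dated {PHI} per the schedule.",
             "Imaging obtained {PHI} without incident.",
             "Follow up arranged for {PHI} at discharge."),
    NAME = c("Attending of record {PHI} reviewed the case.",
             "Family member {PHI} present for teaching.",
             "Handoff received from {PHI} at shift change."),
    AGE = c("A {PHI} year old presenting for evaluation.",
            "Now {PHI} years of age and doing well."),
    ID = c("Account number {PHI} linked to this stay.",
           "Billing reference {PHI} appears on the claim."),
    PHONE = c("Best callback line {PHI} noted in the chart.",
              "Leave results at {PHI} after hours."),
    WEB = c("Results released through {PHI} today."),
    INSTITUTE = c("Prior workup completed at {PHI} last year.",
                  "Outside records faxed by {PHI} this week."),
    STREET = c("Currently staying at {PHI} per intake."),
    CITY = c("Relocated from {PHI} earlier this year."),
    ZIP = c("Residence zip {PHI} updated in registration."))
}

fillers_a <- c(
  "Blood pressure remains stable on the current regimen.",
  "No acute distress was observed during the exam.",
  "Continue aspirin and metformin at present doses.",
  "Chest auscultation was clear bilaterally.",
  "Review of systems was otherwise negative.",
  "Wound site is healing without drainage.",
  "Plan to repeat the basic metabolic panel.",
  "Denies fever chills or night sweats.",
  "Gait steady and unassisted in the hallway.",
  "Immunizations are current per the record.")

fillers_b <- c(
  "Telemetry showed sinus rhythm throughout the night.",
  "Ambulating in the corridor with minimal assistance.",
  "Renal function panel trending toward baseline.",
  "Diet advanced as tolerated without nausea.",
  "Incentive spirometry encouraged every hour.",
  "No erythema noted around the catheter site.",
  "Pain controlled with the scheduled regimen.",
  "Echocardiogram pending at the time of this note.",
  "Social work consulted regarding home services.",
  "Repeat cultures remain negative to date.")

#' Institution style profile for the synthetic generator
#'
#' The two built-in profiles, `"site_A"` and `"site_B"`, emulate two
#' institutions with different documentation conventions: they share no
#' date/phone/ID surface formats, use disjoint name/city/street/institute
#' vocabularies, and phrase their note sentences differently.
#'
#' @param name `"site_A"` or `"site_B"`, or a custom list with the same
#'   fields to pass through.
#' @return A `deid_style` list: `name`, `vocab`, `templates`, `fillers`,
#'   `date_formats`, `phone_formats`, `id_formats`, `header`.
#' @export
style_profile <- function(name = c("site_A", "site_B")) {
  if (is.list(name)) {
    stopifnot(all(c("name", "vocab", "templates", "fillers", "date_formats",
                    "phone_formats", "id_formats", "header") %in% names(name)))
    return(structure(name, class = "deid_style"))
  }
  name <- match.arg(name)
  if (name == "site_A") {
    structure(list(
      name = "site_A", vocab = style_vocab_a(),
      templates = style_templates_a(), fillers = fillers_a,
      date_formats = c("mdY_slash", "mdy_slash"),
      phone_formats = c("paren_dash", "dash"),
      id_formats = c("mrn_dash", "digits7"),
      name_formats = c("first_last", "initial_last"),
      header = c("%s", "Electronic record excerpt for internal review.")),
      class = "deid_style")
  } else {
    structure(list(
      name = "site_B", vocab = style_vocab_b(),
      templates = style_templates_b(), fillers = fillers_b,
      date_formats = c("iso_dash", "monthname"),
      phone_formats = c("dots", "intl_space"),
      id_formats = c("uf_prefix", "digits8_dash"),
      name_formats = c("last_comma_first"),
      header = c("%s", "Unit documentation extract generated on request.")),
      class = "deid_style")
  }
}

.month_abbrev <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug",
                   "Sep", "Oct", "Nov", "Dec")

render_date <- function(fmt) {
  y <- sample(2010:2018, 1); m <- sample(1:12, 1); d <- sample(1:28, 1)
  switch(fmt,
    mdY_slash = sprintf("%02d/%02d/%d", m, d, y),
    mdy_slash = sprintf("%d/%d/%02d", m, d, y %% 100),
    iso_dash = sprintf("%d-%02d-%02d", y, m, d),
    monthname = sprintf("%s %d, %d", .month_abbrev[m], d, y),
    abort(paste0("unknown date format: ", fmt)))
}

render_phone <- function(fmt) {
  a <- sample(200:989, 1); e <- sample(200:989, 1); n <- sample(0:9999, 1)
  switch(fmt,
    paren_dash = sprintf("(%03d) %03d-%04d", a, e, n),
    dash = sprintf("%03d-%03d-%04d", a, e, n),
    dots = sprintf("%03d.%03d.%04d", a, e, n),
    intl_space = sprintf("+1 %03d %03d %04d", a, e, n),
    abort(paste0("unknown phone format: ", fmt)))
}

render_id <- function(fmt) {
  switch(fmt,
    mrn_dash = sprintf("MRN-%06d", sample(0:999999, 1)),
    digits7 = sprintf("%07d", sample(1000000:9999999, 1)),
    uf_prefix = sprintf("UF%06d", sample(0:999999, 1)),
    digits8_dash = sprintf("%08d-%d", sample(10000000:99999999, 1),
                           sample(0:9, 1)),
    abort(paste0("unknown id format: ", fmt)))
}

render_name <- function(fmt, vocab) {
  fn <- sample(vocab$first_names, 1); ln <- sample(vocab$last_names, 1)
  switch(fmt,
    first_last = paste(fn, ln),
    initial_last = paste0(substr(fn, 1, 1), ". ", ln),
    last_comma_first = paste0(toupper(ln), ", ", fn),
    abort(paste0("unknown name format: ", fmt)))
}

render_phi <- function(category, style) {
  v <- style$vocab
  switch(category,
    DATE = render_date(sample(style$date_formats, 1)),
    NAME = render_name(sample(style$name_formats, 1), v),
    AGE = as.character(sample(18:95, 1)),
    ID = render_id(sample(style$id_formats, 1)),
    PHONE = render_phone(sample(style$phone_formats, 1)),
    WEB = sample(v$webs, 1),
    INSTITUTE = sample(v$institutes, 1),
    STREET = paste(sample(100:9999, 1), sample(v$streets, 1)),
    CITY = sample(v$cities, 1),
    ZIP = sample(v$zips, 1),
    abort(paste0("unknown category: ", category)))
}

#' Configuration for the synthetic note generator
#'
#' @param n_notes Number of notes to generate.
#' @param note_type_mix Named weights over note types; the default is
#'   dominated by the three most common clinical note types (progress
#'   notes, radiology reports, history & physical).
#' @param category_weights Named non-negative weights over the ten PHI
#'   categories; the default is proportional to the single-site totals of
#'   [phi_category_counts()], so rare categories (WEB, STREET, ZIP) stay
#'   realistically rare.
#' @param typo_rate Probability that an eligible inter-word space (letters
#'   on both sides, outside every PHI span) is deleted, emulating
#'   run-together typos; annotations stay consistent.
#' @param sentences_mean Mean number of body sentences per note.
#' @param phi_rate Probability that a body sentence carries one PHI slot.
#' @param seed Integer seed; generation is byte-identical for a fixed
#'   configuration and style.
#' @return A `deid_gen_config` list.
#' @export
generator_config <- function(n_notes, note_type_mix = NULL,
                             category_weights = NULL, typo_rate = 0,
                             sentences_mean = 10, phi_rate = 0.7,
                             seed = 1L) {
  stopifnot(n_notes >= 1)
  if (is.null(note_type_mix))
    note_type_mix <- c("PROGRESS NOTES" = 0.40, "RADIOLOGY REPORT" = 0.25,
                       "H&P" = 0.20, "CONSULT" = 0.10,
                       "DISCHARGE SUMMARY" = 0.05)
  if (is.null(category_weights)) {
    counts <- phi_category_counts()
    w <- counts$uf_training + counts$uf_validation + counts$uf_test
    category_weights <- setNames(w, counts$category)
  }
  if (any(category_weights < 0) || sum(category_weights) == 0)
    abort("category_weights must be non-negative with positive sum")
  bad <- setdiff(names(category_weights), phi_categories())
  if (length(bad) > 0)
    abort(paste0("unknown categories in weights: ", paste(bad, collapse = ", ")))
  stopifnot(typo_rate >= 0, typo_rate <= 1)
  structure(list(n_notes = as.integer(n_notes), note_type_mix = note_type_mix,
                 category_weights = category_weights,
                 typo_rate = typo_rate, sentences_mean = sentences_mean,
                 phi_rate = phi_rate, seed = as.integer(seed)),
            class = "deid_gen_config")
}

# Build one note: header lines plus body sentences, one per line; each PHI
# slot's category is drawn iid from the configured weights.
build_note <- function(cfg, style, note_type) {
  wts <- cfg$category_weights / sum(cfg$category_weights)
  cats_avail <- names(wts)[wts > 0]
  for (cat in cats_avail) {
    if (length(style$templates[[cat]]) == 0)
      abort(paste0("style ", style$name, " has no templates for ", cat))
  }
  n_body <- max(3L, stats::rpois(1, cfg$sentences_mean - 2) + 2L)
  lines <- character(0)
  spans <- list()
  offset <- 0L
  push_line <- function(line, span = NULL) {
    if (!is.null(span)) {
      span$start <- span$start + offset
      span$end <- span$end + offset
      spans[[length(spans) + 1L]] <<- span
    }
    lines[[length(lines) + 1L]] <<- line
    offset <<- offset + nchar(line) + 1L  # newline
  }
  push_line(sprintf(style$header[1], note_type))
  push_line(style$header[2])
  for (i in seq_len(n_body)) {
    if (runif(1) < cfg$phi_rate) {
      cat <- sample(names(wts), 1, prob = wts)
      tmpl <- sample(style$templates[[cat]], 1)
      value <- render_phi(cat, style)
      at <- regexpr("{PHI}", tmpl, fixed = TRUE)
      line <- sub("{PHI}", value, tmpl, fixed = TRUE)
      push_line(line, span = list(start = as.integer(at) - 1L,
                                  end = as.integer(at) - 1L + nchar(value),
                                  category = cat, surface = value))
    } else {
      push_line(sample(style$fillers, 1))
    }
  }
  text <- paste(lines, collapse = "\n")
  spans <- if (length(spans) == 0) new_span_tbl() else
    bind_rows(lapply(spans, as_tibble))
  list(text = text, spans = spans)
}

# Delete eligible inter-word spaces at the configured rate, shifting span
# offsets so annotations stay exact. Spaces inside a PHI span are never
# deleted (the surface must stay intact).
inject_typos <- function(text, spans, rate) {
  if (rate <= 0 || nchar(text) < 3) return(list(text = text, spans = spans))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  pos <- which(chars == " ")
  pos <- pos[pos > 1 & pos < n]
  ok <- grepl("[[:alpha:]]", chars[pos - 1]) & grepl("[[:alpha:]]", chars[pos + 1])
  pos <- pos[ok]
  if (nrow(spans) > 0) {
    inside <- vapply(pos, function(p)
      any(spans$start < (p - 1L) & spans$end > p), TRUE)
    pos <- pos[!inside]
  }
  del <- pos[runif(length(pos)) < rate]
  if (length(del) == 0) return(list(text = text, spans = spans))
  del0 <- del - 1L  # 0-based offsets of deleted chars
  text2 <- paste(chars[-del], collapse = "")
  if (nrow(spans) > 0) {
    shift <- function(o) o - vapply(o, function(x) sum(del0 < x), 1L)
    spans$start <- as.integer(shift(spans$start))
    spans$end <- as.integer(shift(spans$end))
  }
  list(text = text2, spans = spans)
}

#' Generate a synthetic annotated corpus
#'
#' Produces surrogate clinical notes with standoff PHI annotations in the
#' requested institution style. Every filled slot is recorded as a span;
#' output is byte-identical for a fixed configuration and style.
#'
#' @param cfg A [generator_config()].
#' @param style A [style_profile()].
#' @return A `deid_corpus`.
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(3, seed = 7), style_profile("site_A"))
#' corp$doc_id
generate_corpus <- function(cfg, style = style_profile("site_A")) {
  stopifnot(inherits(cfg, "deid_gen_config"), inherits(style, "deid_style"))
  rng <- .save_rng()
  on.exit(.restore_rng(rng), add = TRUE)
  set.seed(cfg$seed)
  note_types <- sample(names(cfg$note_type_mix), cfg$n_notes, replace = TRUE,
                       prob = cfg$note_type_mix)
  docs <- lapply(seq_len(cfg$n_notes), function(i) {
    note <- build_note(cfg, style, note_types[i])
    inject_typos(note$text, note$spans, cfg$typo_rate)
  })
  deid_corpus(
    doc_id = sprintf("%s_%04d", style$name, seq_len(cfg$n_notes)),
    text = vapply(docs, `[[`, "", "text"),
    spans = lapply(docs, `[[`, "spans"),
    note_type = note_types)
}

#' Built-in gazetteer dictionaries for a style profile
#'
#' Derives knowledge-base dictionaries (names, cities, zip codes,
#' institutes) from a style profile's vocabulary — the synthetic analogue of
#' local institutional resources. Zip codes are exact-match only.
#'
#' @param style A [style_profile()].
#' @return A list of [dictionary()] objects.
#' @export
builtin_dictionaries <- function(style = style_profile("site_A")) {
  v <- style$vocab
  list(
    dictionary(paste0(style$name, "_cities"), "CITY", v$cities, priority = 1L),
    dictionary(paste0(style$name, "_zips"), "ZIP", v$zips, priority = 1L,
               fuzzy = FALSE),
    dictionary(paste0(style$name, "_names"), "NAME",
               c(v$first_names, v$last_names), priority = 2L),
    dictionary(paste0(style$name, "_institutes"), "INSTITUTE", v$institutes,
               priority = 3L))
}

#' Perturb gold annotations into predictions with known error counts
#'
#' Builds a prediction set realizing exactly the requested counts of each
#' error class: `boundary_mismatch` (same category, offsets shifted),
#' `wrong_category` (same offsets, category changed), `false_positive`
#' (span inserted over unannotated text), `false_negative` (gold span
#' removed). All remaining gold spans are copied unchanged, so
#' [classify_errors()] recovers the planted counts exactly.
#'
#' @param corpus A `deid_corpus` with gold spans.
#' @param spec Named list/vector with any of the four counts.
#' @param seed Seed for choosing which spans to perturb.
#' @return A span tibble (`doc_id`, `start`, `end`, `category`).
#' @export
plant_prediction_errors <- function(corpus, spec = list(), seed = 1L) {
  spec <- as.list(spec)
  for (nm in c("boundary_mismatch", "wrong_category", "false_positive",
               "false_negative"))
    if (is.null(spec[[nm]])) spec[[nm]] <- 0L
  bad <- setdiff(names(spec), c("boundary_mismatch", "wrong_category",
                                "false_positive", "false_negative"))
  if (length(bad) > 0)
    abort(paste0("unknown error classes: ", paste(bad, collapse = ", ")))
  gold <- tidyr::unnest(corpus[, c("doc_id", "spans")], "spans")
  gold$idx <- seq_len(nrow(gold))
  n_perturb <- spec$boundary_mismatch + spec$wrong_category +
    spec$false_negative
  if (n_perturb > nrow(gold))
    abort(sprintf("spec needs %d gold spans but corpus has %d", n_perturb,
                  nrow(gold)))
  rng <- .save_rng()
  on.exit(.restore_rng(rng), add = TRUE)
  set.seed(as.integer(seed))
  draw <- function(x, n) x[sample.int(length(x), n)]  # no 1:x surprise
  wide <- gold$idx[gold$end - gold$start >= 2L]
  if (spec$boundary_mismatch > length(wide))
    abort("not enough multi-character spans for the requested boundary mismatches")
  bm_idx <- if (spec$boundary_mismatch > 0)
    draw(wide, spec$boundary_mismatch) else integer(0)
  rest <- setdiff(gold$idx, bm_idx)
  if (spec$wrong_category + spec$false_negative > length(rest))
    abort("not enough gold spans for the requested error counts")
  pick <- if (length(rest) > 0 && spec$wrong_category + spec$false_negative > 0)
    draw(rest, spec$wrong_category + spec$false_negative) else integer(0)
  wc_idx <- head(pick, spec$wrong_category)
  fn_idx <- tail(pick, spec$false_negative)

  pred <- gold
  if (length(bm_idx) > 0)
    pred$end[pred$idx %in% bm_idx] <- pred$end[pred$idx %in% bm_idx] - 1L
  if (length(wc_idx) > 0) {
    cats <- phi_categories()
    cur <- pred$category[pred$idx %in% wc_idx]
    alt <- vapply(cur, function(cc) cats[cats != cc][1], "")
    pred$category[pred$idx %in% wc_idx] <- alt
  }
  pred <- pred[!(pred$idx %in% fn_idx), , drop = FALSE]

  if (spec$false_positive > 0) {
    inserts <- list()
    need <- spec$false_positive
    for (i in seq_len(nrow(corpus))) {
      if (need == 0) break
      text <- corpus$text[i]
      gsp <- corpus$spans[[i]]
      m <- gregexpr("[[:alpha:]]{4,}", text)[[1]]
      if (m[1] == -1) next
      len <- attr(m, "match.length")
      cand_s <- as.integer(m) - 1L
      cand_e <- cand_s + len
      free <- vapply(seq_along(cand_s), function(k) {
        nrow(gsp) == 0 || !any(gsp$start < cand_e[k] & gsp$end > cand_s[k])
      }, TRUE)
      ks <- which(free)
      if (length(ks) == 0) next
      take <- ks[sample.int(length(ks), min(need, length(ks)))]
      for (k in take) {
        inserts[[length(inserts) + 1L]] <- tibble(
          doc_id = corpus$doc_id[i], start = cand_s[k], end = cand_e[k],
          category = "DATE", surface = substr0(text, cand_s[k], cand_e[k]),
          idx = NA_integer_)
        need <- need - 1L
      }
    }
    if (need > 0)
      abort("not enough unannotated text to place the requested false positives")
    pred <- bind_rows(pred, bind_rows(inserts))
  }
  pred$idx <- NULL
  arrange(pred, .data$doc_id, .data$start)
}
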