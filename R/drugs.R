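#' Dermatology drug catalogue by treatment category
#'
#' The drug lists behind prescription classification, keyed by the five
#' treatment categories used in dermatology prescribing summaries: systemic
#' antipruritics, antibiotics (topical and/or systemic), topical otic
#' preparations, topical skin preparations, and nutritionals. Combination
#' products appear under every category they belong to
#' (e.g. gentamicin/betamethasone is both an antibiotic and an otic).
#' Each drug type prescribed at a visit counts as one treatment course
#' regardless of duration.
#'
#' @return Named list of character vectors, names are the category codes
#'   `antipruritic`, `antibiotic`, `otic`, `topical_skin`, `nutritional`.
#' @export
drug_catalogue <- function() {
  list(
    antipruritic = c(
      "lokivetmab", "chlorpheniramine", "cyclosporine", "dexamethasone",
      "diphenhydramine", "hydroxyzine", "oclacitinib", "prednisone",
      "trimeprazine/prednisone"),
    antibiotic = c(
      "amoxicillin", "amoxicillin/clavulanate", "bacitracin/neomycin/polymyxin",
      "cefadroxil", "cefazolin", "cefovecin", "cefpodoxime", "clindamycin",
      "doxycycline", "enrofloxacin", "enrofloxacin/silver sulfadiazine",
      "gentamicin/betamethasone", "gentamicin/clotrimazole/mometasone",
      "marbofloxacin", "nystatin/neomycin/thiostrepton/triamcinolone acetonide",
      "sulfadimethoxine/ormetoprim", "sulfamethoxazole/trimethoprim"),
    otic = c(
      "acetic acid/boric acid", "acetic acid/hydocortisone",
      "ear cleaner non-medicated", "enrofloxacin/silver sulfadiazine",
      "florfenicol/terbinafine/betamethasone acetate",
      "florfenicol/terbinafine/mometasone furoate",
      "fluocinolone/dimethyl sulfoxide", "gentamicin/betamethasone",
      "gentamicin/clotrimazole/mometasone",
      "ketoconazole/chlorhexidine/tris-edta",
      "tromethamine/disodium edta dihydrate"),
    topical_skin = c(
      "acetic acid/chlorhexidine/ketoconazole", "benzoyl peroxide",
      "benzoyl peroxide/sulfur/salicylic acid", "chlorhexidine/climbazole",
      "chlorhexidine/tromethamine/disodium edta dihydrate",
      "conditioner non-medicated", "hydrocortisone/aluminum acetate",
      "nystatin/neomycin/thiostrepton/triamcinolone acetonide",
      "sulfur/salicylic acid"),
    nutritional = c(
      "dermatology diet", "fish oil/omega fatty acids/vitamin e")
  )
}

#' Classify a drug name into a treatment category
#'
#' Case-insensitive lookup against [drug_catalogue()]. Drugs listed under
#' several categories (combination products such as
#' enrofloxacin/silver sulfadiazine) resolve by the prescription `context`
#' when one is given; otherwise by the fixed priority
#' otic > topical_skin > antibiotic > antipruritic > nutritional.
#' Unknown names return `"unclassified"`.
#'
#' @param drug_name Character vector of drug names.
#' @param context Optional category hint (one of the category codes),
#'   recycled along `drug_name`; used only where the drug is actually listed
#'   under that category.
#' @return Character vector of category codes (or `"unclassified"`).
#' @examples
#' classify_drug("Oclacitinib")               # antipruritic
#' classify_drug("gentamicin/betamethasone")  # otic (dual-listed, priority)
#' @export
classify_drug <- function(drug_name, context = NULL) {
  catalogue <- drug_catalogue()
  priority <- c("otic", "topical_skin", "antibiotic", "antipruritic", "nutritional")
  key <- tolower(trimws(drug_name))
  if (!is.null(context)) context <- rep_len(as.character(context), length(key))
  vapply(seq_along(key), function(i) {
    hits <- priority[vapply(priority, function(cat) key[i] %in% catalogue[[cat]],
                            logical(1))]
    if (!length(hits)) return("unclassified")
    if (!is.null(context) && !is.na(context[i]) && context[i] %in% hits)
      return(context[i])
    hits[1]
  }, character(1))
}
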