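# First-match threshold rule lists over the eigenvalue spectrum.
#
# A rule is a conjunction of comparisons lambda_i OP 10^T, with T stored as
# a log10 constant exactly as published. Comparisons are evaluated in the
# linear domain (lambda vs 10^T) so that zero eigenvalues need no log; the
# log10 view is only used for reporting. The first rule whose conjuncts all
# hold decides the label; a default label applies when none fires.

#' Build a threshold rule
#'
#' @param conjuncts list of conditions, each `list(lambda = i, op = "<",
#'   log10_threshold = T)` with `i` in 1..8 and `op` one of `<`, `<=`, `>=`,
#'   `>`.
#' @param label label assigned when all conjuncts hold: `"AC"` or `"UN"`.
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(conjuncts, label) {
  stopifnot(label %in% c("AC", "UN"), length(conjuncts) >= 1L)
  conjuncts <- lapply(conjuncts, function(cj) {
    if (!is.numeric(cj$lambda) || cj$lambda < 1 || cj$lambda > 8)
      stop_input("threshold_rule: eigenvalue index must be in 1..8")
    if (!cj$op %in% c("<", "<=", ">=", ">"))
      stop_input("threshold_rule: unknown comparator '%s'", cj$op)
    if (!is.finite(cj$log10_threshold))
      stop_input("threshold_rule: threshold must be finite")
    list(lambda = as.integer(cj$lambda), op = cj$op,
         log10_threshold = as.numeric(cj$log10_threshold))
  })
  structure(list(conjuncts = conjuncts, label = label), class = "threshold_rule")
}

#' Build an ordered rule set
#'
#' @param rules list of [threshold_rule()] objects, evaluated in order.
#' @param default label when no rule fires.
#' @param name short model name.
#' @param notes free-text provenance notes carried into the registry file.
#' @return A `rule_set` object.
#' @export
rule_set <- function(rules, default = "AC", name = "custom", notes = NULL) {
  stopifnot(default %in% c("AC", "UN"))
  rules <- lapply(rules, function(r) {
    if (!inherits(r, "threshold_rule")) r <- threshold_rule(r$conjuncts, r$label)
    r
  })
  structure(list(name = name, rules = rules, default = default,
                 notes = notes %||% character()),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat(sprintf("<rule_set> %s: %d rule(s), default %s\n",
              x$name, length(x$rules), x$default))
  for (i in seq_along(x$rules)) {
    r <- x$rules[[i]]
    conds <- vapply(r$conjuncts, function(cj)
      sprintf("log10(lambda%d) %s %.4g", cj$lambda, cj$op, cj$log10_threshold), "")
    cat(sprintf("  %d. %s => %s\n", i, paste(conds, collapse = " AND "), r$label))
  }
  invisible(x)
}

#' Apply a rule set to an eigenvalue spectrum
#'
#' @param rules a [rule_set()].
#' @param spectrum an [eigen_spectrum()] (length 8, descending).
#' @return `list(label, rule_index)`; `rule_index` is `NA` when the default
#'   label applied.
#' @export
apply_rule_set <- function(rules, spectrum) {
  lam <- as.numeric(spectrum)
  for (i in seq_along(rules$rules)) {
    r <- rules$rules[[i]]
    hit <- all(vapply(r$conjuncts, function(cj) {
      thr <- 10^cj$log10_threshold
      switch(cj$op,
             "<"  = lam[cj$lambda] <  thr,
             "<=" = lam[cj$lambda] <= thr,
             ">=" = lam[cj$lambda] >= thr,
             ">"  = lam[cj$lambda] >  thr)
    }, NA))
    if (hit) return(list(label = r$label, rule_index = i))
  }
  list(label = rules$default, rule_index = NA_integer_)
}

#' Published CART rule list
#'
#' The CART tree only inspects the extreme eigenvalues: a collapsed
#' spectrum (`log10(lambda_8) < 0.145`, a near-rank-deficient covariance as
#' caused by a flat or disconnected lead) is Unacceptable, as is an inflated
#' one (`log10(lambda_1) >= 5.08`, high-power artifacts); everything else is
#' Acceptable.
#'
#' @return A [rule_set()].
#' @export
cart_rules <- function() {
  rule_set(list(
    threshold_rule(list(list(lambda = 8, op = "<", log10_threshold = 0.145)), "UN"),
    threshold_rule(list(list(lambda = 1, op = ">=", log10_threshold = 5.08)), "UN")),
    default = "AC", name = "cart",
    notes = "Comparator symbols as printed (strict < on lambda8, >= on lambda1).")
}

#' Published C4.5 rule list
#'
#' Refines CART's treatment of large `lambda_1` records: after rejecting
#' collapsed spectra, records with moderate total energy
#' (`log10(lambda_1) <= 4.86`) are accepted, extreme ones
#' (`log10(lambda_1) >= 7.91`) rejected, and the remainder decided on
#' `lambda_6` — energy outside the three dominant cardiac components
#' (`log10(lambda_6) >= 2.23`) indicates several unexpected noise sources.
#'
#' @return A [rule_set()].
#' @export
c45_rules <- function() {
  rule_set(list(
    threshold_rule(list(list(lambda = 8, op = "<=", log10_threshold = 0.0870)), "UN"),
    threshold_rule(list(list(lambda = 1, op = "<=", log10_threshold = 4.86)), "AC"),
    threshold_rule(list(list(lambda = 1, op = ">=", log10_threshold = 7.91)), "UN"),
    threshold_rule(list(list(lambda = 6, op = ">=", log10_threshold = 2.23)), "UN")),
    default = "AC", name = "c45",
    notes = paste("Tree topology reconstructed from the published narrative;",
                  "lambda6 above threshold rejects (excess energy outside the",
                  "three dominant components); non-strict comparators where",
                  "the source is silent."))
}

#' Published RIPPER rule list
#'
#' First-match rule list: collapsed spectrum rejects; then two conjunctions
#' over the dominant subspace (`lambda_1` with `lambda_3`, then `lambda_1`
#' with `lambda_2`) catch records whose leading eigenvalues are jointly
#' inflated by artifacts; the default accepts.
#'
#' @return A [rule_set()].
#' @export
ripper_rules <- function() {
  rule_set(list(
    threshold_rule(list(list(lambda = 8, op = "<=", log10_threshold = 0.0863)), "UN"),
    threshold_rule(list(list(lambda = 1, op = ">=", log10_threshold = 4.85),
                        list(lambda = 3, op = ">=", log10_threshold = 4.06)), "UN"),
    threshold_rule(list(list(lambda = 1, op = ">=", log10_threshold = 5.09),
                        list(lambda = 2, op = ">=", log10_threshold = 3.75)), "UN")),
    default = "AC", name = "ripper",
    notes = "First rule that fires decides the label.")
}

#' Classify a spectrum with the published CART rules
#' @param spectrum an [eigen_spectrum()].
#' @return `"AC"` or `"UN"`.
#' @export
classify_cart <- function(spectrum) apply_rule_set(cart_rules(), spectrum)$label

#' Classify a spectrum with the published C4.5 rules
#' @inheritParams classify_cart
#' @return `"AC"` or `"UN"`.
#' @export
classify_c45 <- function(spectrum) apply_rule_set(c45_rules(), spectrum)$label

#' Classify a spectrum with the published RIPPER rules
#' @inheritParams classify_cart
#' @return `"AC"` or `"UN"`.
#' @export
classify_ripper <- function(spectrum) apply_rule_set(ripper_rules(), spectrum)$label

#' Look up a shipped rule set by model name
#' @param model `"cart"`, `"c45"` or `"ripper"`.
#' @return A [rule_set()].
#' @export
get_rule_set <- function(model) {
  switch(model,
         cart = cart_rules(), c45 = c45_rules(), ripper = ripper_rules(),
         stop_input("unknown model '%s' (expected cart, c45 or ripper)", model))
}

#' Write a rule set to a JSON registry file
#'
#' Thresholds are serialized at full double precision so that a read/write
#' cycle is bit-exact.
#'
#' @param rules a [rule_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_rule_registry <- function(rules, path) {
  obj <- list(
    format = "ecgsqc-rule-registry-v1",
    name = rules$name,
    default = rules$default,
    notes = as.character(rules$notes),
    rules = lapply(rules$rules, function(r) list(
      label = r$label,
      conjuncts = lapply(r$conjuncts, function(cj) list(
        lambda = as.integer(cj$lambda), op = cj$op,
        log10_threshold = cj$log10_threshold)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a rule set from a JSON registry file
#' @param path registry path written by [write_rule_registry()].
#' @return A [rule_set()].
#' @export
read_rule_registry <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ecgsqc-rule-registry-v1"))
    stop_input("read_rule_registry: %s is not a rule registry file", path)
  rules <- lapply(obj$rules, function(r)
    threshold_rule(lapply(r$conjuncts, function(cj)
      list(lambda = cj$lambda, op = cj$op, log10_threshold = cj$log10_threshold)),
      r$label))
  rule_set(rules, default = obj$default, name = obj$name,
           notes = unlist(obj$notes) %||% character())
}
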