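#' Stoichiometric metabolic model
#'
#' Minimal constraint-based model container: stoichiometric matrix
#' (metabolites x reactions), flux bounds, objective coefficients, and the
#' designated biomass, sucrose-uptake and levansucrase-synthesis reactions
#' used by the dynamic-model coupling.
#'
#' @param S numeric matrix, metabolites in rows, reactions in columns.
#'   Dimnames are used as metabolite/reaction ids if `mets`/`rxns` absent.
#' @param mets,rxns character ids.
#' @param lb,ub lower/upper flux bounds, mmol/(gDW h).
#' @param obj objective coefficients (default: 1 on the biomass reaction).
#' @param biomass_id,uptake_id,levansucrase_id designated reaction ids;
#'   `levansucrase_id` may be `NA` if the model has not been augmented yet.
#' @return An object of class `stoich_model`.
#' @export
stoich_model <- function(S, mets = rownames(S), rxns = colnames(S),
                         lb, ub, obj = NULL,
                         biomass_id, uptake_id, levansucrase_id = NA) {
  S <- as.matrix(S)
  if (is.null(mets) || is.null(rxns)) abort("metabolite and reaction ids required")
  if (nrow(S) != length(mets) || ncol(S) != length(rxns)) {
    abort("S dimensions inconsistent with id lists")
  }
  if (length(lb) != ncol(S) || length(ub) != ncol(S)) {
    abort("bounds must have one entry per reaction")
  }
  if (any(lb > ub)) abort("lower bounds must be <= upper bounds")
  if (anyDuplicated(rxns) || anyDuplicated(mets)) abort("duplicate ids")
  if (!biomass_id %in% rxns) abort("biomass reaction not found")
  if (!uptake_id %in% rxns) abort("sucrose uptake reaction not found")
  if (!is.na(levansucrase_id) && !levansucrase_id %in% rxns) {
    abort(paste0("levansucrase reaction '", levansucrase_id,
                 "' not found; candidates: ", paste(rxns, collapse = ", ")))
  }
  if (is.null(obj)) obj <- as.numeric(rxns == biomass_id)
  dimnames(S) <- list(mets, rxns)
  structure(list(S = S, mets = mets, rxns = rxns,
                 lb = setNames(as.numeric(lb), rxns),
                 ub = setNames(as.numeric(ub), rxns),
                 obj = setNames(as.numeric(obj), rxns),
                 biomass_id = biomass_id, uptake_id = uptake_id,
                 levansucrase_id = levansucrase_id),
            class = "stoich_model")
}

#' @export
print.stoich_model <- function(x, ...) {
  cat(sprintf("<stoich_model> %d metabolites x %d reactions\n",
              length(x$mets), length(x$rxns)))
  cat("  biomass:", x$biomass_id, "| uptake:", x$uptake_id,
      "| levansucrase:", x$levansucrase_id, "\n")
  invisible(x)
}

#' Add or remove a reaction
#'
#' @param m a `stoich_model`.
#' @param id reaction id.
#' @param stoich named numeric vector: metabolite id -> coefficient
#'   (negative = consumed). Unknown metabolite ids are an error.
#' @param lb,ub flux bounds for the new reaction.
#' @return The modified `stoich_model`.
#' @export
add_reaction <- function(m, id, stoich, lb = 0, ub = 1000) {
  stopifnot(inherits(m, "stoich_model"))
  if (id %in% m$rxns) abort(paste0("reaction '", id, "' already present"))
  unknown <- setdiff(names(stoich), m$mets)
  if (length(unknown)) {
    abort(paste("unknown metabolite ids:", paste(unknown, collapse = ", ")))
  }
  col <- setNames(numeric(length(m$mets)), m$mets)
  col[names(stoich)] <- stoich
  stoich_model(cbind(m$S, setNames(data.frame(col), id)),
               mets = m$mets, rxns = c(m$rxns, id),
               lb = c(m$lb, lb), ub = c(m$ub, ub),
               obj = c(m$obj, 0),
               biomass_id = m$biomass_id, uptake_id = m$uptake_id,
               levansucrase_id = m$levansucrase_id)
}

#' @rdname add_reaction
#' @export
remove_reaction <- function(m, id) {
  stopifnot(inherits(m, "stoich_model"))
  if (!id %in% m$rxns) abort(paste0("reaction '", id, "' not found"))
  keep <- setdiff(m$rxns, id)
  lvs <- if (identical(m$levansucrase_id, id)) NA else m$levansucrase_id
  stoich_model(m$S[, keep, drop = FALSE], mets = m$mets, rxns = keep,
               lb = m$lb[keep], ub = m$ub[keep], obj = m$obj[keep],
               biomass_id = m$biomass_id, uptake_id = m$uptake_id,
               levansucrase_id = lvs)
}

#' Add the levansucrase protein-synthesis pseudo-reaction
#'
#' Adds a pseudo-reaction draining amino-acid precursors and energy
#' equivalents per mmol of levansucrase protein, a levansucrase species,
#' and a secretion exchange. The composition is configurable; the true
#' residue-level stoichiometry of the secreted protein is not published,
#' so the default is a uniform placeholder and must be treated as
#' non-authoritative.
#'
#' @param m a `stoich_model` lacking the pseudo-reaction.
#' @param composition named numeric vector of metabolite costs per mmol
#'   protein (negative = consumed), e.g. `c(aa = -2, atp = -1)`.
#' @param id id for the synthesis pseudo-reaction.
#' @param product_id id for the levansucrase protein species.
#' @param exchange_id id for the secretion exchange.
#' @return The augmented `stoich_model` with `levansucrase_id` set.
#' @export
augment_levansucrase <- function(m, composition = c(aa = -2, atp = -1),
                                 id = "LVS_SYN", product_id = "lvs",
                                 exchange_id = "EX_lvs") {
  stopifnot(inherits(m, "stoich_model"))
  if (!is.na(m$levansucrase_id)) {
    abort("model already has a levansucrase synthesis reaction")
  }
  if (any(composition >= 0)) {
    abort("composition entries are costs and must be negative")
  }
  unknown <- setdiff(names(composition), m$mets)
  if (length(unknown)) {
    abort(paste("composition references unknown metabolite ids:",
                paste(unknown, collapse = ", ")))
  }
  S2 <- rbind(m$S, setNames(data.frame(t(numeric(length(m$rxns)))), m$rxns))
  rownames(S2) <- c(m$mets, product_id)
  m2 <- stoich_model(as.matrix(S2), mets = c(m$mets, product_id),
                     rxns = m$rxns, lb = m$lb, ub = m$ub, obj = m$obj,
                     biomass_id = m$biomass_id, uptake_id = m$uptake_id)
  m2 <- add_reaction(m2, id, c(composition, setNames(1, product_id)))
  m2 <- add_reaction(m2, exchange_id, setNames(-1, product_id))
  m2$levansucrase_id <- id
  m2
}

#' Drop the levansucrase augmentation again
#'
#' Inverse of [augment_levansucrase()] at the id level.
#'
#' @inheritParams augment_levansucrase
#' @return The de-augmented `stoich_model`.
#' @export
deaugment_levansucrase <- function(m, id = "LVS_SYN", product_id = "lvs",
                                   exchange_id = "EX_lvs") {
  m <- remove_reaction(m, exchange_id)
  m <- remove_reaction(m, id)
  keep <- setdiff(m$mets, product_id)
  stoich_model(m$S[keep, , drop = FALSE], mets = keep, rxns = m$rxns,
               lb = m$lb, ub = m$ub, obj = m$obj,
               biomass_id = m$biomass_id, uptake_id = m$uptake_id,
               levansucrase_id = NA)
}
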