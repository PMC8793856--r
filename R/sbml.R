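SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
SBML_GROUPS_NS <- "http://www.sbml.org/sbml/level3/version1/groups/version1"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

#' Read an SBML Level 3 (fbc) constraint-based model
#'
#' Parses species, compartments, reactions with fbc flux bounds, fbc gene
#' product associations (GPR rules), EC number annotations (MIRIAM
#' `ec-code` resources), subsystem labels from the SBML groups package, and
#' the active fbc objective (taken as the biomass reaction). Models without
#' fbc gene associations load with all GPRs absent (with a warning); missing
#' fbc bounds fall back to `[-1000, 1000]` for reversible and `[0, 1000]`
#' for irreversible reactions.
#'
#' @param path path to an SBML file.
#' @param require_biomass error if no active objective identifies a biomass
#'   reaction.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path, require_biomass = FALSE) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in '", path, "': ", conditionMessage(e))
  })

  find_all <- function(node, name) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  }
  model_node <- find_all(doc, "model")
  if (length(model_node) == 0) stop("malformed SBML: no <model> element")
  model_node <- model_node[[1]]

  comp_nodes <- find_all(model_node, "compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- find_all(model_node, "species")
  if (length(sp_nodes) == 0) stop("malformed SBML: no <species> elements")
  charge <- suppressWarnings(
    as.integer(xml2::xml_attr(sp_nodes, "charge")))
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"),
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    formula = xml2::xml_attr(sp_nodes, "chemicalFormula"),
    charge = charge,
    stringsAsFactors = FALSE)
  if (anyNA(metabolites$id)) stop("malformed SBML: species without id")

  params <- find_all(model_node, "parameter")
  param_val <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))

  gp_nodes <- find_all(model_node, "geneProduct")
  gp_label <- setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")),
           xml2::xml_attr(gp_nodes, "id"),
           xml2::xml_attr(gp_nodes, "label")),
    xml2::xml_attr(gp_nodes, "id"))

  rxn_nodes <- find_all(model_node, "reaction")
  if (length(rxn_nodes) == 0) stop("malformed SBML: no <reaction> elements")
  n_rxn <- length(rxn_nodes)
  rxn_ids <- xml2::xml_attr(rxn_nodes, "id")
  if (anyNA(rxn_ids)) stop("malformed SBML: reaction without id")

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- ub <- numeric(n_rxn)
  gpr <- character(n_rxn)
  ec <- vector("list", n_rxn)
  met_index <- setNames(seq_len(nrow(metabolites)), metabolites$id)

  for (j in seq_len(n_rxn)) {
    node <- rxn_nodes[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      if (length(refs)) {
        sp <- xml2::xml_attr(refs, "species")
        if (anyNA(met_index[sp])) {
          stop("malformed SBML: reaction '", rxn_ids[j],
               "' references unknown species ",
               paste(sp[is.na(met_index[sp])], collapse = ", "))
        }
        st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        st[is.na(st)] <- 1
        ii <- c(ii, unname(met_index[sp]))
        jj <- c(jj, rep(j, length(refs)))
        xx <- c(xx, sign * st)
      }
    }
    lb_id <- xml2::xml_attr(node, "lowerFluxBound")
    ub_id <- xml2::xml_attr(node, "upperFluxBound")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[j] <- if (!is.na(lb_id) && lb_id %in% names(param_val)) {
      param_val[[lb_id]]
    } else if (reversible) -1000 else 0
    ub[j] <- if (!is.na(ub_id) && ub_id %in% names(param_val)) {
      param_val[[ub_id]]
    } else 1000

    assoc <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']")
    gpr[j] <- if (inherits(assoc, "xml_missing")) "" else {
      gpr_to_string(sbml_parse_association(
        xml2::xml_find_first(assoc, "./*"), gp_label))
    }
    res <- xml2::xml_find_all(node, ".//*[local-name()='li']")
    urls <- xml2::xml_attr(res, "resource")
    urls <- urls[!is.na(urls) & grepl("ec-code", urls)]
    ec[[j]] <- sub(".*ec-code[:/]", "", urls)
  }
  if (all(!nzchar(gpr))) {
    warning("SBML model carries no fbc gene product associations; ",
            "all GPRs absent")
  }

  subsystem <- rep(NA_character_, n_rxn)
  for (grp in find_all(model_node, "group")) {
    grp_name <- xml2::xml_attr(grp, "name")
    members <- xml2::xml_attr(find_all(grp, "member"), "idRef")
    subsystem[match(members, rxn_ids)] <- grp_name
  }

  biomass_id <- NA_character_
  active <- xml2::xml_attr(
    xml2::xml_find_first(model_node, ".//*[local-name()='listOfObjectives']"),
    "activeObjective")
  fo <- find_all(model_node, "fluxObjective")
  if (length(fo)) biomass_id <- xml2::xml_attr(fo, "reaction")[1]
  if (require_biomass && is.na(biomass_id)) {
    stop("SBML model declares no active flux objective (biomass reaction)")
  }

  reactions <- data.frame(
    id = rxn_ids,
    name = ifelse(is.na(xml2::xml_attr(rxn_nodes, "name")), rxn_ids,
                  xml2::xml_attr(rxn_nodes, "name")),
    lower_bound = lb, upper_bound = ub,
    subsystem = subsystem, gpr = gpr,
    stringsAsFactors = FALSE)
  reactions$ec <- ec

  metabolic_model(
    id = xml2::xml_attr(model_node, "id") %|na|% "model",
    metabolites = metabolites,
    reactions = reactions,
    S = Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(nrow(metabolites), n_rxn)),
    biomass_reaction_id = biomass_id,
    compartments = compartments)
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

sbml_parse_association <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    lab <- if (gp %in% names(gp_label)) gp_label[[gp]] else gp
    return(structure(list(op = "gene", gene = lab), class = "gpr_expr"))
  }
  children <- lapply(xml2::xml_children(node), sbml_parse_association,
                     gp_label = gp_label)
  gpr_node(if (nm == "and") "and" else "or", children)
}

#' Write a model to SBML Level 3 with fbc and groups
#'
#' The counterpart of [read_sbml()]: emits fbc flux bound parameters, gene
#' products and gene product associations, EC annotations as MIRIAM
#' `ec-code` resources, subsystems as a groups partonomy, and the biomass
#' reaction as the active fbc objective.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  root <- xml2::xml_new_root(
    "sbml",
    "xmlns" = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    "xmlns:groups" = SBML_GROUPS_NS,
    "xmlns:rdf" = RDF_NS, "xmlns:bqbiol" = BQBIOL_NS,
    level = "3", version = "1",
    "fbc:required" = "false", "groups:required" = "false")
  mnode <- xml2::xml_add_child(root, "model", id = model$id,
                               "fbc:strict" = "true")

  loc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cid in model$compartments) {
    xml2::xml_add_child(loc, "compartment", id = cid, constant = "true")
  }

  los <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (k in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[k, ]
    sp <- xml2::xml_add_child(
      los, "species", id = m$id, name = m$name, compartment = m$compartment,
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (!is.null(m$formula) && !is.na(m$formula)) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
    }
    if (!is.null(m$charge) && !is.na(m$charge)) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(m$charge))
    }
  }

  bounds <- unique(c(model$reactions$lower_bound, model$reactions$upper_bound))
  bound_key <- vapply(bounds, format, character(1), digits = 17)
  bound_id <- setNames(sprintf("flux_bound_%d", seq_along(bounds)), bound_key)
  lop <- xml2::xml_add_child(mnode, "listOfParameters")
  for (b in seq_along(bounds)) {
    xml2::xml_add_child(lop, "parameter", id = bound_id[[b]],
                        value = format(bounds[b], digits = 17),
                        constant = "true", sboTerm = "SBO:0000626")
  }

  genes <- model$genes
  if (length(genes)) {
    logp <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(logp, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", g), "fbc:label" = g)
    }
  }

  lor <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nrow(model$reactions))) {
    r <- model$reactions[j, ]
    rnode <- xml2::xml_add_child(
      lor, "reaction", id = r$id, name = r$name, metaid = paste0("meta_", r$id),
      reversible = tolower(r$lower_bound < 0), fast = "false",
      "fbc:lowerFluxBound" = bound_id[[format(r$lower_bound, digits = 17)]],
      "fbc:upperFluxBound" = bound_id[[format(r$upper_bound, digits = 17)]])
    ecs <- model$reactions$ec[[j]]
    if (length(ecs)) {
      ann <- xml2::xml_add_child(rnode, "annotation")
      rdf <- xml2::xml_add_child(ann, "rdf:RDF")
      desc <- xml2::xml_add_child(rdf, "rdf:Description",
                                  "rdf:about" = paste0("#meta_", r$id))
      bag <- xml2::xml_add_child(xml2::xml_add_child(desc, "bqbiol:is"),
                                 "rdf:Bag")
      for (e in ecs) {
        xml2::xml_add_child(bag, "rdf:li", "rdf:resource" =
                              paste0("https://identifiers.org/ec-code/", e))
      }
    }
    stoich <- model$S[, j]
    subs <- which(stoich < 0); prods <- which(stoich > 0)
    if (length(subs)) {
      lref <- xml2::xml_add_child(rnode, "listOfReactants")
      for (k in subs) {
        xml2::xml_add_child(lref, "speciesReference",
                            species = model$metabolites$id[k],
                            stoichiometry = format(-stoich[k], digits = 17),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lref <- xml2::xml_add_child(rnode, "listOfProducts")
      for (k in prods) {
        xml2::xml_add_child(lref, "speciesReference",
                            species = model$metabolites$id[k],
                            stoichiometry = format(stoich[k], digits = 17),
                            constant = "true")
      }
    }
    if (!is.null(model$gprs[[r$id]])) {
      assoc <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      sbml_write_association(assoc, model$gprs[[r$id]])
    }
  }

  if (!is.na(model$biomass_reaction_id)) {
    loo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    objn <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                                "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(objn, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = model$biomass_reaction_id,
                        "fbc:coefficient" = "1")
  }

  subsys <- model$reactions$subsystem
  if (any(!is.na(subsys))) {
    log_ <- xml2::xml_add_child(mnode, "groups:listOfGroups")
    for (s in unique(subsys[!is.na(subsys)])) {
      grp <- xml2::xml_add_child(
        log_, "groups:group",
        "groups:id" = gsub("[^A-Za-z0-9_]", "_", paste0("group_", s)),
        "groups:name" = s, "groups:kind" = "partonomy")
      lom <- xml2::xml_add_child(grp, "groups:listOfMembers")
      for (rid in model$reactions$id[which(subsys == s)]) {
        xml2::xml_add_child(lom, "groups:member", "groups:idRef" = rid)
      }
    }
  }

  xml2::write_xml(root, path)
  invisible(path)
}

sbml_write_association <- function(parent, expr) {
  if (expr$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", expr$gene))
    return(invisible(NULL))
  }
  node <- xml2::xml_add_child(parent, paste0("fbc:", expr$op))
  for (a in expr$args) sbml_write_association(node, a)
  invisible(NULL)
}
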