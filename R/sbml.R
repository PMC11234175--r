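#' @include codegen.R
NULL

## MathML string builders --------------------------------------------------

.ml_cn <- function(x) sprintf("<cn type=\"real\"> %s </cn>", .num(x))
.ml_ci <- function(x) sprintf("<ci> %s </ci>", x)
.ml_time <- function()
  paste0("<csymbol encoding=\"text\" definitionURL=",
         "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>")
.ml_apply <- function(op, ...)
  sprintf("<apply><%s/>%s</apply>", op, paste0(..., collapse = ""))

## nested Horner polynomial a + dt (b + dt (c + d dt)), dt = t - t0
.ml_poly <- function(cf, t0) {
  dt <- .ml_apply("minus", .ml_time(), .ml_cn(t0))
  inner <- .ml_cn(cf[4])
  inner <- .ml_apply("plus", .ml_cn(cf[3]), .ml_apply("times", dt, inner))
  inner <- .ml_apply("plus", .ml_cn(cf[2]), .ml_apply("times", dt, inner))
  .ml_apply("plus", .ml_cn(cf[1]), .ml_apply("times", dt, inner))
}

## profile as piecewise cubic with constant extrapolation, clipped at 0
.ml_profile <- function(p) {
  k <- p@knots
  pieces <- sprintf("<piece>%s%s</piece>", .ml_cn(p@values[1]),
                    .ml_apply("lt", .ml_time(), .ml_cn(k[1])))
  for (i in seq_len(length(k) - 1L)) {
    cond <- .ml_apply("and",
                      .ml_apply("geq", .ml_time(), .ml_cn(k[i])),
                      .ml_apply("lt", .ml_time(), .ml_cn(k[i + 1])))
    pieces <- c(pieces, sprintf("<piece>%s%s</piece>", .ml_poly(p@coefs[i, ], k[i]), cond))
  }
  pw <- sprintf("<piecewise>%s<otherwise>%s</otherwise></piecewise>",
                paste0(pieces, collapse = ""), .ml_cn(p@values[length(k)]))
  .ml_apply("max", .ml_cn(0), pw)
}

.sbml_id <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.math <- function(body)
  sprintf("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">%s</math>", body)

#' Export a dynamic model as SBML Level 3
#'
#' Writes the model as an SBML Level 3 Version 2 document: compartments with
#' relative sizes, species with initial concentrations, reactions with
#' kinetic laws in extent units (concentration rate times reference
#' compartment volume), enzymes as modifiers. mRNA forcing profiles are
#' encoded as assignment rules over piecewise cubic interpolation of the
#' embedded spline coefficients (clipped at zero, constant beyond the
#' measured window). Translocation events become SBML events whose
#' assignments move the conserved amount and switch on an indicator
#' parameter gating the first-order return reaction.
#'
#' @param model a [DynamicModel-class]
#' @param path optional file path to write the document to
#' @return an `xml2::xml_document`, invisibly when `path` is given
#' @export
exportSBML <- function(model, path = NULL) {
  asm <- .assemble(model)
  net <- model@network
  sn <- asm$stateNames
  sid <- .sbml_id(sn)
  if (anyDuplicated(sid))
    stop("species keys collide after SBML id sanitization", call. = FALSE)
  idx2sid <- sid

  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))

  push("<?xml version=\"1.0\" encoding=\"UTF-8\"?>")
  push("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version2/core\" level=\"3\" version=\"2\">")
  push("<model id=\"cell_type_model\" timeUnits=\"hour\">")
  push("<listOfUnitDefinitions><unitDefinition id=\"hour\"><listOfUnits>")
  push("<unit kind=\"second\" exponent=\"1\" scale=\"0\" multiplier=\"3600\"/>")
  push("</listOfUnits></unitDefinition></listOfUnitDefinitions>")

  push("<listOfCompartments>")
  cmp <- net@compartments
  for (i in seq_len(nrow(cmp)))
    push("<compartment id=\"%s\" size=\"%s\" spatialDimensions=\"3\" constant=\"true\"/>",
         .sbml_id(cmp$id[i]), .num(cmp$volume[i]))
  push("</listOfCompartments>")

  sp <- net@species[net@species$role != "mRNA", , drop = FALSE]
  push("<listOfSpecies>")
  for (i in seq_len(nrow(sp)))
    push(paste0("<species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
                "initialConcentration=\"%s\" hasOnlySubstanceUnits=\"false\" ",
                "boundaryCondition=\"false\" constant=\"false\"/>"),
         sid[i], sp$name[i], .sbml_id(sp$compartment[i]), .num(sp$initial[i]))
  push("</listOfSpecies>")

  ## forcing parameters + armed-return indicators
  plan <- .emission_plan(model, tEnd = 24, grid = 0:1, rtol = 1e-8, atol = 1e-10)
  genes <- names(model@profiles)
  push("<listOfParameters>")
  for (g in genes)
    push("<parameter id=\"m_%s\" value=\"%s\" constant=\"false\"/>",
         .sbml_id(g), .num(model@profiles[[g]]@values[1]))
  for (k in seq_along(plan$returns))
    push("<parameter id=\"armed_%d\" value=\"0\" constant=\"false\"/>", k)
  push("</listOfParameters>")

  if (length(genes)) {
    push("<listOfRules>")
    for (g in genes)
      push("<assignmentRule variable=\"m_%s\">%s</assignmentRule>",
           .sbml_id(g), .math(.ml_profile(model@profiles[[g]])))
    push("</listOfRules>")
  }

  vol <- asm$vol
  push("<listOfReactions>")
  rxns <- net@reactions
  for (j in seq_along(rxns)) {
    r <- rxns[[j]]
    push("<reaction id=\"%s\" reversible=\"false\">", .sbml_id(r@id))
    if (length(r@substrates)) {
      push("<listOfReactants>")
      for (k in names(r@substrates))
        push("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
             .sbml_id(k), .num(r@substrates[[k]]))
      push("</listOfReactants>")
    }
    if (length(r@products)) {
      push("<listOfProducts>")
      for (k in names(r@products))
        push("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
             .sbml_id(k), .num(r@products[[k]]))
      push("</listOfProducts>")
    }
    if (!is.na(r@enzyme))
      push("<listOfModifiers><modifierSpeciesReference species=\"%s\"/></listOfModifiers>",
           .sbml_id(r@enzyme))

    refk <- if (length(r@substrates)) names(r@substrates)[1] else names(r@products)[1]
    vref <- .ml_cn(vol[[refk]])
    p <- r@rateLaw@params
    law <- switch(r@rateLaw@form,
      michaelis_menten = {
        S <- .ml_ci(.sbml_id(names(r@substrates)[1]))
        E <- .ml_ci(.sbml_id(r@enzyme))
        .ml_apply("divide",
                  .ml_apply("times", .ml_cn(p[["kcat"]]), E, S, vref),
                  .ml_apply("plus", .ml_cn(p[["Km"]]), S))
      },
      mass_action = {
        terms <- lapply(names(r@substrates), function(k)
          if (r@substrates[[k]] == 1) .ml_ci(.sbml_id(k)) else
            .ml_apply("power", .ml_ci(.sbml_id(k)), .ml_cn(r@substrates[[k]])))
        .ml_apply("times", .ml_cn(p[["k"]]), paste0(unlist(terms), collapse = ""), vref)
      },
      transport_first_order = ,
      degradation_first_order =
        .ml_apply("times", .ml_cn(p[["k"]]),
                  .ml_ci(.sbml_id(names(r@substrates)[1])), vref),
      translation =
        .ml_apply("times", .ml_cn(p[["ks"]]), .ml_ci(paste0("m_", .sbml_id(r@gene))), vref),
      stop("rate-law form not expressible in SBML export: ", r@rateLaw@form))
    push("<kineticLaw>%s</kineticLaw>", .math(law))
    push("</reaction>")
  }

  ## gated first-order return reactions for armed translocations
  for (k in seq_along(plan$returns)) {
    r <- plan$returns[[k]]
    srck <- sn[r$src]; dstk <- sn[r$dst]
    push("<reaction id=\"ret_%d\" reversible=\"false\">", k)
    push("<listOfReactants><speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/></listOfReactants>",
         idx2sid[r$dst])
    push("<listOfProducts><speciesReference species=\"%s\" stoichiometry=\"1\" constant=\"true\"/></listOfProducts>",
         idx2sid[r$src])
    law <- .ml_apply("times", .ml_ci(sprintf("armed_%d", k)), .ml_cn(r$k_ret),
                     .ml_ci(idx2sid[r$dst]), .ml_cn(vol[[dstk]]))
    push("<kineticLaw>%s</kineticLaw>", .math(law))
    push("</reaction>")
  }
  push("</listOfReactions>")

  if (length(plan$events)) {
    push("<listOfEvents>")
    for (i in seq_along(plan$events)) {
      e <- plan$events[[i]]
      if (!length(e$actions)) next
      push("<event id=\"ev_%d\" useValuesFromTriggerTime=\"true\">", i)
      push("<trigger initialValue=\"true\" persistent=\"true\">%s</trigger>",
           .math(.ml_apply("geq", .ml_time(), .ml_cn(e$time))))
      push("<listOfEventAssignments>")
      for (a in e$actions) {
        if (a$op == "add") {
          push("<eventAssignment variable=\"%s\">%s</eventAssignment>",
               idx2sid[a$idx],
               .math(.ml_apply("plus", .ml_ci(idx2sid[a$idx]), .ml_cn(a$amount))))
        } else {
          push("<eventAssignment variable=\"%s\">%s</eventAssignment>",
               idx2sid[a$dst],
               .math(.ml_apply("plus", .ml_ci(idx2sid[a$dst]),
                               .ml_apply("times", .ml_cn(a$fraction * a$vratio),
                                         .ml_ci(idx2sid[a$src])))))
          push("<eventAssignment variable=\"%s\">%s</eventAssignment>",
               idx2sid[a$src],
               .math(.ml_apply("times", .ml_cn(1 - a$fraction), .ml_ci(idx2sid[a$src]))))
          push("<eventAssignment variable=\"armed_%d\">%s</eventAssignment>",
               a$arm, .math(.ml_cn(1)))
        }
      }
      push("</listOfEventAssignments>")
      push("</event>")
    }
    push("</listOfEvents>")
  }

  push("</model>")
  push("</sbml>")

  doc <- xml2::read_xml(paste(lines, collapse = "\n"))
  v <- validateSBMLDocument(doc)
  if (nrow(v))
    stop("exported SBML failed validation:\n",
         paste(sprintf("  [%s] %s", v$rule, v$message), collapse = "\n"),
         call. = FALSE)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Structurally validate an SBML document
#'
#' Checks the constraints the export relies on: Level 3 core namespace, a
#' single model, unique compartment/species/parameter/reaction ids, species
#' referencing declared compartments, reactions and rules referencing
#' declared species/parameters, and a kinetic law on every reaction.
#'
#' @param doc an `xml2::xml_document` or a path to an SBML file
#' @return data.frame of violations (`element`, `rule`, `message`); zero
#'   rows means the document passes.
#' @export
validateSBMLDocument <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  v <- list()
  add <- function(...) v[[length(v) + 1L]] <<- .violation(...)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  root <- xml2::xml_name(doc)
  if (root != "sbml") add("<root>", "sbml_root", "root element is not <sbml>")
  model <- xml2::xml_find_all(doc, "./s:model", ns)
  if (length(model) != 1) {
    add("<root>", "one_model", "document must contain exactly one <model>")
    return(do.call(rbind, v))
  }
  getids <- function(xp) xml2::xml_attr(xml2::xml_find_all(doc, xp, ns), "id")
  cids <- getids(".//s:listOfCompartments/s:compartment")
  spn <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sids <- xml2::xml_attr(spn, "id")
  pids <- getids(".//s:listOfParameters/s:parameter")
  rxn <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rids <- xml2::xml_attr(rxn, "id")
  for (set in list(c("compartment", list(cids)), c("species", list(sids)),
                   c("parameter", list(pids)), c("reaction", list(rids)))) {
    dups <- unique(set[[2]][duplicated(set[[2]])])
    for (d in dups) add(d, "unique_ids", sprintf("duplicated %s id '%s'", set[[1]], d))
  }
  for (i in seq_along(spn)) {
    cref <- xml2::xml_attr(spn[[i]], "compartment")
    if (!cref %in% cids)
      add(sids[i], "species_compartment",
          sprintf("species '%s' references undeclared compartment '%s'", sids[i], cref))
  }
  for (i in seq_along(rxn)) {
    refs <- xml2::xml_attr(
      xml2::xml_find_all(rxn[[i]], ".//s:speciesReference | .//s:modifierSpeciesReference", ns),
      "species")
    for (m in setdiff(refs, sids))
      add(rids[i], "reaction_species",
          sprintf("reaction '%s' references undeclared species '%s'", rids[i], m))
    if (length(xml2::xml_find_all(rxn[[i]], "./s:kineticLaw", ns)) != 1)
      add(rids[i], "kinetic_law", sprintf("reaction '%s' lacks a kinetic law", rids[i]))
  }
  rules <- xml2::xml_find_all(doc, ".//s:listOfRules/s:assignmentRule", ns)
  for (r in rules) {
    var <- xml2::xml_attr(r, "variable")
    if (!var %in% c(pids, sids))
      add(var, "rule_variable",
          sprintf("assignment rule targets undeclared variable '%s'", var))
  }
  if (length(v)) do.call(rbind, v) else
    .violation(character(0), character(0), character(0))
}
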