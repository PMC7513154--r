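# Benchmark structures bundled as code: the Asia and Alarm networks
# (structure only; parameterize with random_cpts() or user CPT files) and
# a four-node toy chain/fork used in examples and tests.

asia_arcs <- function() rbind(
  c("asia", "tub"), c("smoke", "lung"), c("smoke", "bronc"),
  c("tub", "either"), c("lung", "either"), c("either", "xray"),
  c("either", "dysp"), c("bronc", "dysp"))

asia_nodes <- function()
  c("asia", "tub", "smoke", "lung", "bronc", "either", "xray", "dysp")

alarm_spec <- function() {
  # child ~ parents; standard 37-node / 46-arc monitoring network
  list(
    arities = c(
      HYPOVOLEMIA = 2L, LVFAILURE = 2L, LVEDVOLUME = 3L, CVP = 3L,
      PCWP = 3L, HISTORY = 2L, STROKEVOLUME = 3L, ERRLOWOUTPUT = 2L,
      ERRCAUTER = 2L, INSUFFANESTH = 2L, ANAPHYLAXIS = 2L, TPR = 3L,
      PULMEMBOLUS = 2L, PAP = 3L, INTUBATION = 3L, SHUNT = 2L,
      FIO2 = 2L, PVSAT = 3L, SAO2 = 3L, MINVOLSET = 3L, VENTMACH = 4L,
      DISCONNECT = 2L, VENTTUBE = 4L, KINKEDTUBE = 2L, VENTLUNG = 4L,
      VENTALV = 4L, ARTCO2 = 3L, EXPCO2 = 4L, MINVOL = 4L, PRESS = 4L,
      CATECHOL = 2L, HR = 3L, HRBP = 3L, HREKG = 3L, HRSAT = 3L,
      CO = 3L, BP = 3L),
    parents = list(
      LVEDVOLUME = c("HYPOVOLEMIA", "LVFAILURE"),
      CVP = "LVEDVOLUME", PCWP = "LVEDVOLUME", HISTORY = "LVFAILURE",
      STROKEVOLUME = c("HYPOVOLEMIA", "LVFAILURE"),
      CO = c("HR", "STROKEVOLUME"), BP = c("CO", "TPR"),
      TPR = "ANAPHYLAXIS",
      CATECHOL = c("ARTCO2", "INSUFFANESTH", "SAO2", "TPR"),
      HR = "CATECHOL", HRBP = c("ERRLOWOUTPUT", "HR"),
      HREKG = c("ERRCAUTER", "HR"), HRSAT = c("ERRCAUTER", "HR"),
      PAP = "PULMEMBOLUS", SHUNT = c("INTUBATION", "PULMEMBOLUS"),
      SAO2 = c("PVSAT", "SHUNT"), PVSAT = c("FIO2", "VENTALV"),
      ARTCO2 = "VENTALV", EXPCO2 = c("ARTCO2", "VENTLUNG"),
      VENTALV = c("INTUBATION", "VENTLUNG"),
      MINVOL = c("INTUBATION", "VENTLUNG"),
      VENTLUNG = c("INTUBATION", "KINKEDTUBE", "VENTTUBE"),
      VENTTUBE = c("DISCONNECT", "VENTMACH"),
      VENTMACH = "MINVOLSET",
      PRESS = c("INTUBATION", "KINKEDTUBE", "VENTTUBE")))
}

#' Load a bundled benchmark structure
#'
#' Available fixtures: `"asia"` (8 nodes, 8 arcs, all binary), `"alarm"`
#' (37 nodes, 46 arcs, arities 2-4) and `"fig1"` (4-node toy with arcs
#' A -> B, B -> C, B -> D).  Only the structures are bundled; conditional
#' probability tables are not part of the benchmark definition here --
#' parameterize with [random_cpts()] or supply CPT files via
#' [read_network()].
#'
#' @param name fixture name.
#' @return a `bn_dag`; attribute `"arities"` carries the standard state
#'   counts.
#' @export
load_fixture <- function(name = c("asia", "alarm", "fig1")) {
  name <- match.arg(name)
  if (name == "asia") {
    g <- dag(asia_nodes(), asia_arcs())
    attr(g, "arities") <- stats::setNames(rep(2L, 8L), asia_nodes())
  } else if (name == "alarm") {
    sp <- alarm_spec()
    nodes <- names(sp$arities)
    arcs <- do.call(rbind, lapply(names(sp$parents), function(ch)
      cbind(sp$parents[[ch]], ch)))
    g <- dag(nodes, arcs)
    attr(g, "arities") <- sp$arities
  } else {
    g <- dag(c("A", "B", "C", "D"),
             rbind(c("A", "B"), c("B", "C"), c("B", "D")))
    attr(g, "arities") <- c(A = 2L, B = 2L, C = 2L, D = 2L)
  }
  g
}
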