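# Built-in lateral-inhibition fixture.

#' Delta-Notch lateral-inhibition epithelium
#'
#' Builds the two-marker Boolean model of juxtacrine lateral inhibition and
#' places it on a hexagonal grid. Each cell carries two markers: `Green`, an
#' integration input set directly by the neighbourhood rule (the received
#' juxtacrine signal), and the internal `Red` marker, induced at low `Green`
#' (`Red := !Green`). A cell thus adopts the Red fate exactly when its
#' neighbourhood signal is off, and in turn silences that fate in the cells
#' that sense it - lateral inhibition. The rule variants differ in how the
#' neighbourhood signal is integrated:
#' \describe{
#'   \item{`contact1`}{`Red>=1 [1:1] atleast 1` - at least one contacting
#'     cell is Red (classical Delta-Notch; stable patterns put the Red cells
#'     on a maximal independent set of the grid graph).}
#'   \item{`contactall`}{`Red>=1 [1:1] all` - every contacting cell is Red
#'     (reverted, mostly-Red patterns).}
#'   \item{`dist3-12`}{`Red>=1 [1:3] atleast 12` - at least 12 cells at
#'     distance up to 3 are Red (coarser patterning).}
#' }
#' All cells start with both internal markers at 0. The default simulation
#' settings are alpha-asynchronous with `alpha = 0.25`.
#'
#' @param width,height Grid dimensions.
#' @param wrap `"none"`, `"horizontal"`, `"vertical"` or `"torus"`.
#' @param rule Integration rule variant (see above).
#' @param alpha Update fraction for the default configuration.
#' @param seed Seed for the default configuration.
#' @param max_steps Step bound for the default configuration.
#' @return List with elements `epithelium` and `config`.
#' @examples
#' fx <- fixture_delta_notch(1, 2)   # the two-cell system
#' run_simulation(fx$epithelium, scheme = "synchronous")
#' @export
fixture_delta_notch <- function(width = 50, height = 50,
                                wrap = c("none", "horizontal", "vertical", "torus"),
                                rule = c("contact1", "contactall", "dist3-12"),
                                alpha = 0.25, seed = 1L, max_steps = 1000L) {
  wrap <- match.arg(wrap)
  rule <- match.arg(rule)
  topo <- hex_topology(width, height,
                       wrap_horizontal = wrap %in% c("horizontal", "torus"),
                       wrap_vertical = wrap %in% c("vertical", "torus"))
  model <- logical_model(
    components = c(Green = 1, Red = 1),
    inputs = "Green",
    functions = list(Red = "!Green"),
    name = "delta_notch")
  rule_text <- switch(rule,
    contact1 = "Red>=1 [1:1] atleast 1",
    contactall = "Red>=1 [1:1] all",
    `dist3-12` = "Red>=1 [1:3] atleast 12")
  epi <- epithelium(topo, model,
                    integration = list(Green = rule_text),
                    initial = NULL)
  cfg <- simulation_config(scheme = "alpha", alpha = alpha, seed = seed,
                           max_steps = max_steps)
  list(epithelium = epi, config = cfg)
}
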