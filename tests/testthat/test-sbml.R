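# Hand-written SBML qual document for the three-component lateral-inhibition
# cell (input nb_Red; Green := nb_Red >= 1; Red := Green < 1), used as an
# import oracle: the parsed model must reproduce the truth table.
sbml_dn3 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">
  <model id="dn3">
    <qual:listOfQualitativeSpecies>
      <qual:qualitativeSpecies qual:id="nb_Red" qual:maxLevel="1" qual:constant="true"/>
      <qual:qualitativeSpecies qual:id="Green" qual:maxLevel="1" qual:constant="false"/>
      <qual:qualitativeSpecies qual:id="Red" qual:maxLevel="1" qual:constant="false"/>
    </qual:listOfQualitativeSpecies>
    <qual:listOfTransitions>
      <qual:transition qual:id="tr_Green">
        <qual:listOfInputs>
          <qual:input qual:qualitativeSpecies="nb_Red" qual:transitionEffect="none"/>
        </qual:listOfInputs>
        <qual:listOfOutputs>
          <qual:output qual:qualitativeSpecies="Green" qual:transitionEffect="assignmentLevel"/>
        </qual:listOfOutputs>
        <qual:listOfFunctionTerms>
          <qual:defaultTerm qual:resultLevel="0"/>
          <qual:functionTerm qual:resultLevel="1">
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><geq/><ci> nb_Red </ci><cn type="integer"> 1 </cn></apply>
            </math>
          </qual:functionTerm>
        </qual:listOfFunctionTerms>
      </qual:transition>
      <qual:transition qual:id="tr_Red">
        <qual:listOfInputs>
          <qual:input qual:qualitativeSpecies="Green" qual:transitionEffect="none"/>
        </qual:listOfInputs>
        <qual:listOfOutputs>
          <qual:output qual:qualitativeSpecies="Red" qual:transitionEffect="assignmentLevel"/>
        </qual:listOfOutputs>
        <qual:listOfFunctionTerms>
          <qual:defaultTerm qual:resultLevel="0"/>
          <qual:functionTerm qual:resultLevel="1">
            <math xmlns="http://www.w3.org/1998/Math/MathML">
              <apply><lt/><ci> Green </ci><cn type="integer"> 1 </cn></apply>
            </math>
          </qual:functionTerm>
        </qual:listOfFunctionTerms>
      </qual:transition>
    </qual:listOfTransitions>
  </model>
</sbml>'

test_that("SBML qual import identifies inputs and reproduces the truth table", {
  m <- read_sbml_qual(sbml_dn3)
  expect_s3_class(m, "logical_model")
  expect_equal(m$components$name, c("nb_Red", "Green", "Red"))
  expect_equal(m$components$is_input, c(TRUE, FALSE, FALSE))
  expect_equal(m$components$max_level, c(1L, 1L, 1L))

  states <- enumerate_states(m)
  for (i in seq_len(nrow(states))) {
    s <- states[i, ]
    expect_equal(update_cell(m, s), oracle_cell_step("dn3", s),
                 info = paste(s, collapse = ","))
  }
})

test_that("species without transitions become an all-input model", {
  doc <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">
  <model id="io"><qual:listOfQualitativeSpecies>
    <qual:qualitativeSpecies qual:id="X" qual:maxLevel="2"/>
    <qual:qualitativeSpecies qual:id="Y"/>
  </qual:listOfQualitativeSpecies></model></sbml>'
  m <- read_sbml_qual(doc)
  expect_true(all(m$components$is_input))
  expect_length(m$functions, 0)
  expect_equal(m$components$max_level, c(2L, 1L))  # maxLevel defaults to 1
  # with no internal components every state is vacuously stable
  expect_true(is_cell_stable(m, c(X = 2, Y = 0)))
})

test_that("write-then-read round-trips model structure", {
  for (m in list(dn3_model(), mv_model(),
                 fixture_delta_notch(2, 2)$epithelium$models[[1]])) {
    path <- withr::local_tempfile(fileext = ".sbml")
    write_sbml_qual(m, path)
    m2 <- read_sbml_qual(path)
    expect_equal(m2$components, m$components, info = m$name)
    expect_equal(m2$functions, m$functions, info = m$name)
    expect_equal(m2$name, m$name)
  }
})

test_that("MathML comparisons normalise to the >=, =, < atom algebra", {
  wrap_math <- function(math) sprintf('<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">
  <model id="t"><qual:listOfQualitativeSpecies>
    <qual:qualitativeSpecies qual:id="A" qual:maxLevel="3"/>
    <qual:qualitativeSpecies qual:id="B" qual:maxLevel="3"/>
  </qual:listOfQualitativeSpecies>
  <qual:listOfTransitions><qual:transition qual:id="tr_B">
    <qual:listOfOutputs><qual:output qual:qualitativeSpecies="B"/></qual:listOfOutputs>
    <qual:listOfFunctionTerms><qual:defaultTerm qual:resultLevel="0"/>
      <qual:functionTerm qual:resultLevel="1">
        <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>
      </qual:functionTerm>
    </qual:listOfFunctionTerms>
  </qual:transition></qual:listOfTransitions></model></sbml>', math)
  f1 <- function(math) read_sbml_qual(wrap_math(math))$functions$B[[1]]$expr

  expect_equal(f1("<apply><gt/><ci>A</ci><cn>1</cn></apply>"),
               parse_logic_expression("A>=2"))
  expect_equal(f1("<apply><leq/><ci>A</ci><cn>2</cn></apply>"),
               parse_logic_expression("A<3"))
  expect_equal(f1("<apply><eq/><ci>A</ci><cn>2</cn></apply>"),
               parse_logic_expression("A=2"))
  # reversed operand order: 2 <= A means A >= 2
  expect_equal(f1("<apply><leq/><cn>2</cn><ci>A</ci></apply>"),
               parse_logic_expression("A>=2"))
  expect_equal(f1("<apply><and/><apply><geq/><ci>A</ci><cn>1</cn></apply><true/></apply>"),
               parse_logic_expression("A>=1 & true"))
  expect_error(f1("<apply><plus/><ci>A</ci><cn>1</cn></apply>"), "unsupported")
  expect_error(f1("<apply><geq/><ci>Z</ci><cn>1</cn></apply>"), "unknown species")
})

test_that("malformed documents fail with a named element", {
  dup <- gsub('qual:id="Red"', 'qual:id="Green"', sbml_dn3)
  expect_error(read_sbml_qual(dup), "duplicate")
  nospecies <- '<?xml version="1.0"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1"
      xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" qual:required="true">
  <model id="e"/></sbml>'
  expect_error(read_sbml_qual(nospecies), "no qualitativeSpecies")
})
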