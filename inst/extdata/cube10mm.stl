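solid airwaymorph
facet normal 0 0 -1
  outer loop
    vertex 0 0 0
    vertex 0 10 0
    vertex 10 10 0
  endloop
endfacet
facet normal 0 0 1
  outer loop
    vertex 0 0 10
    vertex 10 0 10
    vertex 10 10 10
  endloop
endfacet
facet normal 0 -1 0
  outer loop
    vertex 0 0 0
    vertex 10 0 0
    vertex 10 0 10
  endloop
endfacet
facet normal 0 1 0
  outer loop
    vertex 0 10 0
    vertex 0 10 10
    vertex 10 10 10
  endloop
endfacet
facet normal -1 0 0
  outer loop
    vertex 0 0 0
    vertex 0 0 10
    vertex 0 10 10
  endloop
endfacet
facet normal 1 0 0
  outer loop
    vertex 10 0 0
    vertex 10 10 0
    vertex 10 10 10
  endloop
endfacet
facet normal 0 0 -1
  outer loop
    vertex 0 0 0
    vertex 10 10 0
    vertex 10 0 0
  endloop
endfacet
facet normal 0 0 1
  outer loop
    vertex 0 0 10
    vertex 10 10 10
    vertex 0 10 10
  endloop
endfacet
facet normal 0 -1 0
  outer loop
    vertex 0 0 0
    vertex 10 0 10
    vertex 0 0 10
  endloop
endfacet
facet normal 0 1 0
  outer loop
    vertex 0 10 0
    vertex 10 10 10
    vertex 10 10 0
  endloop
endfacet
facet normal -1 0 0
  outer loop
    vertex 0 0 0
    vertex 0 10 10
    vertex 0 10 0
  endloop
endfacet
facet normal 1 0 0
  outer loop
    vertex 10 0 0
    vertex 10 10 10
    vertex 10 0 10
  endloop
endfacet
endsolid airwaymorph
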