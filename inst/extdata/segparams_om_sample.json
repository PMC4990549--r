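{"pixelSize":0.25,"preprocess":{"invert":true,"smooth":false,"histEq":true,"deconv":false},"extendedMin":[0.185621176470588,0.392156862745098],"priorFilters":{"minSize":6.473,"solidityMin":0.84,"ellipticityMin":0.21},"myelin":{"nAngles":72,"rmaxFactor":3,"maxStep":1,"smoothWindow":5,"thicknessTol":0.5,"gRatioRange":[0.4,1]},"blockSize":512,"overlapFraction":0.2,"edgeMargin":2,"classifier":null}
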