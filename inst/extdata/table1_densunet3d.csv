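block,h,w,d,channels,conv_spec
Input,224,224,8,NA,-
Convolution 1,112,112,4,96,7x7x7x96 conv
Pooling,56,56,2,NA,3x3x3 max pooling
Dense block 1,56,56,2,NA,(1x1x1x128 conv)x3 (3x3x3x32 conv)x3
Transition layer 1,28,28,2,NA,1x1x1 conv; 2x2x1 average pooling
Dense block 2,28,28,2,NA,(1x1x1x128 conv)x4 (3x3x3x32 conv)x4
Transition layer 2,14,14,2,NA,1x1x1 conv; 2x2x1 average pooling
Dense block 3,14,14,2,NA,(1x1x1x128 conv)x12 (3x3x3x32 conv)x12
Transition layer 3,7,7,2,NA,1x1x1 conv; 2x2x1 average pooling
Dense block 4,7,7,2,NA,(1x1x1x128 conv)x8 (3x3x3x32 conv)x8
Upsampling layer 1,7,7,2,504,2x2x1x504 upconv
Sum with dense block 3,14,14,2,NA,-
Upsampling layer 2,14,14,2,224,2x2x1x224 upconv
Sum with dense block 2,28,28,2,NA,-
Upsampling layer 3,28,28,2,192,2x2x1x192 upconv
Sum with dense block 1,56,56,2,NA,-
Upsampling layer 4,56,56,2,96,2x2x2x96 upconv
Sum with convolution 1,112,112,4,NA,-
Upsampling layer 5,224,224,8,64,2x2x2x64 upconv
Output,224,224,8,3,1x1x1x3 conv
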